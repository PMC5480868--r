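#' Default region table for the 67-nucleotide guanine-riboswitch aptamer
#'
#' A reconstruction of the assignment of author-numbered nucleotides 15-81
#' to the secondary-structure regions P1/P2/P3, loops L2/L3 and joining
#' strands J1/2, J2/3, J3/1, anchored by the published landmarks: the
#' terminal P1 set \{15-19, 77-81\}, the upper (34/37/61/65) and lower
#' (33/38/60/66) loop base quadruples, and the binding triplet
#' \{47, 51, 74\}. Users with the authoritative assignment should supply
#' their own table to [assign_regions()].
#'
#' @return A tibble with columns `resid`, `region`.
#' @export
default_region_table <- function() {
  seg <- function(ids, region) tibble(resid = as.integer(ids), region = region)
  bind_rows(
    seg(15:21, "P1"), seg(22:24, "J1/2"),
    seg(25:32, "P2"), seg(33:38, "L2"), seg(39:46, "P2"),
    seg(47:52, "J2/3"),
    seg(53:59, "P3"), seg(60:66, "L3"), seg(67:73, "P3"),
    seg(74, "J3/1"), seg(75:81, "P1")) %>%
    arrange(.data$resid)
}

region_levels <- function() c("P1", "P2", "P3", "L2", "L3",
                              "J1/2", "J2/3", "J3/1")

#' Named nucleotide sets used throughout the analyses
#' @return Named list of integer vectors: `terminal_P1`, `upper_quadruple`,
#'   `lower_quadruple`, `binding`.
#' @export
named_nucleotide_sets <- function() {
  list(terminal_P1 = c(15:19, 77:81),
       upper_quadruple = c(34L, 37L, 61L, 65L),
       lower_quadruple = c(33L, 38L, 60L, 66L),
       binding = c(47L, 51L, 74L))
}

#' Assign nucleotides to secondary-structure regions
#'
#' @param structure An `rna_structure`.
#' @param table Optional region table (data frame with columns resid,
#'   region, or a path to two-column delimited text). Entries override the
#'   defaults of [default_region_table()].
#' @return A `region_map`: a tibble (resid, region) covering every
#'   nucleotide of the structure, with the named sets of
#'   [named_nucleotide_sets()] (intersected with the mapped nucleotides)
#'   attached as the `named_sets` attribute.
#' @export
assign_regions <- function(structure, table = NULL) {
  stopifnot(inherits(structure, "rna_structure"))
  if (is.null(table)) {
    tab <- default_region_table()
  } else {
    # a user-supplied table replaces the defaults and must be complete
    if (is.character(table)) table <- read_region_table(table)
    tab <- as_tibble(table)
    names(tab)[1:2] <- c("resid", "region")
    tab <- arrange(tab, .data$resid)
  }
  ids <- structure$nucleotides$resid
  missing <- setdiff(ids, tab$resid)
  if (length(missing) > 0) {
    abort(paste("nucleotide(s) missing from region table:",
                paste(missing, collapse = ", ")))
  }
  map <- tab %>% filter(.data$resid %in% ids)
  if (anyDuplicated(map$resid)) abort("region table maps a nucleotide twice")
  sets <- lapply(named_nucleotide_sets(), function(s) intersect(s, ids))
  structure(map, class = c("region_map", class(map)), named_sets = sets)
}

#' @rdname assign_regions
#' @param path Path to two-column delimited text (nucleotide_id, region).
#' @export
read_region_table <- function(path) {
  tab <- read.table(path, header = FALSE, col.names = c("resid", "region"),
                    stringsAsFactors = FALSE)
  as_tibble(tab)
}

#' Nucleotides belonging to a region
#' @param region_map A `region_map`.
#' @param regions Character vector of region labels, or a named set
#'   (`"terminal_P1"`, `"upper_quadruple"`, `"lower_quadruple"`,
#'   `"binding"`).
#' @return Integer vector of nucleotide ids.
#' @export
region_nucleotides <- function(region_map, regions) {
  sets <- attr(region_map, "named_sets")
  if (length(regions) == 1 && regions %in% names(sets)) {
    return(sets[[regions]])
  }
  region_map$resid[region_map$region %in% regions]
}
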