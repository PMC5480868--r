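# autoplot methods for the main result types; all return ggplot objects

#' @export
autoplot.plrc_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$resid, y = .data$p_lrc)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "nucleotide", y = expression(p[lrc]),
         title = attr(object, "condition")) +
    theme_bw()
}

#' @export
autoplot.delta_profile <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$resid, y = .data$delta_plrc)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "nucleotide", y = expression(Delta * p[lrc])) +
    theme_bw()
  if (!all(is.na(object$sem))) {
    p <- p + geom_errorbar(aes(ymin = .data$delta_plrc - .data$sem,
                               ymax = .data$delta_plrc + .data$sem),
                           width = 0.3, colour = "grey40")
  }
  p
}

#' @export
autoplot.coop_result <- function(object, ...) {
  p <- ggplot(object, aes(x = factor(.data$resid), y = .data$coop)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_col(fill = "steelblue") +
    labs(x = "nucleotide", y = "Coop") +
    theme_bw()
  if (!all(is.na(object$sem))) {
    p <- p + geom_errorbar(aes(ymin = .data$coop - .data$sem,
                               ymax = .data$coop + .data$sem), width = 0.3)
  }
  p
}

#' @export
autoplot.rmsf_profile <- function(object, ...) {
  p <- ggplot(object, aes(x = .data$resid, y = .data$rmsf)) +
    geom_line() +
    labs(x = "nucleotide", y = "RMSF (Å)") +
    theme_bw()
  if (!all(is.na(object$sem))) {
    p <- p + geom_errorbar(aes(ymin = .data$rmsf - .data$sem,
                               ymax = .data$rmsf + .data$sem),
                           width = 0.3, colour = "grey40")
  }
  p
}

#' @export
autoplot.rmsd_series <- function(object, ...) {
  xvar <- if (all(is.na(object$time))) "frame" else "time"
  ggplot(object, aes(x = .data[[xvar]], y = .data$rmsd)) +
    geom_line() +
    labs(x = if (xvar == "time") "time (ps)" else "frame",
         y = "RMSD (Å)") +
    theme_bw()
}

#' @export
autoplot.rac_curve <- function(object, ...) {
  ggplot(object, aes(x = .data$window, y = .data$rac)) +
    geom_line() + geom_point(size = 0.8) +
    labs(x = "window length (frames)", y = "RAC (Å)") +
    theme_bw()
}

#' @export
autoplot.pca_projection <- function(object, components = c(1, 2), ...) {
  pcs <- paste0("PC", components)
  ggplot(object$projections,
         aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]],
             colour = factor(.data$ensemble))) +
    geom_point(alpha = 0.6, size = 0.8) +
    labs(colour = "trajectory") +
    facet_wrap(~half, labeller = ggplot2::label_both) +
    theme_bw()
}

#' @export
autoplot.hydration_series <- function(object, ...) {
  counts <- object %>%
    group_by(.data$frame) %>%
    summarise(hexahydrated = sum(.data$hexahydrated), .groups = "drop")
  ggplot(counts, aes(x = .data$frame, y = .data$hexahydrated)) +
    geom_line() +
    labs(x = "frame", y = "hexahydrated Mg2+ count") +
    theme_bw()
}
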