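# S3 methods for fitted pocket models.

#' @export
print.pocketqsar <- function(x, ...) {
  tab <- table(x$probes$kind)
  cat("Pocket model:", length(x$probes), "probes (",
      paste(names(tab), tab, collapse = ", "), ")\n")
  cat(sprintf("Training: %d ligands, f = %.3f (D = %.3f, P = %.3f, R = %.3f, C = %.3f, N = %d)\n",
              length(x$training_pools), x$objective$f, x$objective$terms$D,
              x$objective$terms$P, x$objective$terms$R, x$objective$terms$C,
              x$objective$terms$N))
  cat(sprintf("Training fit: tau = %.3f, MAE = %.3f pKi\n",
              x$training_report$tau, x$training_report$mae))
  invisible(x)
}

#' @export
summary.pocketqsar <- function(object, ...) {
  res <- residuals(object)
  out <- list(
    n_probes = length(object$probes),
    probe_kinds = table(object$probes$kind),
    n_training = length(object$training_pools),
    objective = object$objective,
    training_report = object$training_report,
    residual_summary = summary(res),
    distributions = object$distributions,
    envelope_spheres = length(object$envelope$radii))
  class(out) <- "summary.pocketqsar"
  out
}

#' @export
print.summary.pocketqsar <- function(x, ...) {
  cat("Induced pocket model\n")
  cat("  probes:", x$n_probes, "(",
      paste(names(x$probe_kinds), x$probe_kinds, collapse = ", "), ")\n")
  cat("  training ligands:", x$n_training, "\n")
  t <- x$objective$terms
  cat(sprintf("  objective f = %.3f: D = %.3f, P = %.3f, R = %.3f, C = %.3f, N = %d\n",
              x$objective$f, t$D, t$P, t$R, t$C, t$N))
  cat(sprintf("  training tau = %.3f, MAE = %.3f pKi, parsimony = %.3f\n",
              x$training_report$tau, x$training_report$mae,
              x$training_report$parsimony))
  cat("  residuals (observed - fitted):\n")
  print(x$residual_summary)
  d <- x$distributions
  cat(sprintf("  quality distributions: conf N(%.3f, %.3f), nov N(%.3f, %.3f), excl N(%.3f, %.3f)\n",
              d$confidence$mu, d$confidence$sigma, d$novelty$mu,
              d$novelty$sigma, d$exclusion$mu, d$exclusion$sigma))
  invisible(x)
}

#' Probe table of a fitted pocket model
#'
#' @param object a `pocketqsar`.
#' @param ... unused.
#' @return Data frame: kind, x, y, z, dx, dy, dz, weight.
#' @export
coef.pocketqsar <- function(object, ...) {
  p <- object$probes
  data.frame(kind = p$kind, x = p$position[, 1], y = p$position[, 2],
             z = p$position[, 3], dx = p$direction[, 1],
             dy = p$direction[, 2], dz = p$direction[, 3],
             weight = p$weight, stringsAsFactors = FALSE)
}

#' @export
fitted.pocketqsar <- function(object, ...) object$training_scores

#' @export
residuals.pocketqsar <- function(object, ...) {
  object$activities[names(object$training_scores)] - object$training_scores
}

#' Plot a fitted pocket model
#'
#' A 2D projection (default xy) of probe positions, envelope sphere
#' centers, and training optimal poses.
#'
#' @param x a `pocketqsar`.
#' @param dims which two coordinates to show (default c(1, 2)).
#' @param ... passed to `plot`.
#' @export
plot.pocketqsar <- function(x, dims = c(1, 2), ...) {
  env <- x$envelope$centers[, dims, drop = FALSE]
  prb <- x$probes$position[, dims, drop = FALSE]
  lab <- c("x", "y", "z")[dims]
  plot(env, col = adjustcolor("grey70", 0.5), pch = 16, cex = 0.8,
       xlab = paste0(lab[1], " (A)"), ylab = paste0(lab[2], " (A)"),
       main = "Pocket model", asp = 1, ...)
  cols <- c(steric = "black", donor = "blue", acceptor = "red")
  points(prb, col = cols[x$probes$kind], pch = 17, cex = 1.4)
  legend("topright", bty = "n",
         legend = c("envelope atoms", "steric probe", "donor probe",
                    "acceptor probe"),
         col = c("grey70", cols), pch = c(16, 17, 17, 17))
  invisible(x)
}
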