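# Sensitivity of PM13Scores to controlled structural and chemical noise:
# random coordinate perturbation at a prescribed RMSD, and random
# re-assignment of atomic group labels.

.perturb_once <- function(atoms, target_rmsd) {
  n <- nrow(atoms)
  if (target_rmsd == 0) return(atoms)
  disp <- matrix(stats::rnorm(3 * n), n, 3)
  scale <- target_rmsd / sqrt(mean(rowSums(disp^2)))
  atoms[, c("x", "y", "z")] <- as.matrix(atoms[, c("x", "y", "z")]) +
    disp * scale
  atoms
}

#' Perturb a pocket's coordinates to an exact RMSD
#'
#' Adds i.i.d. Gaussian displacements to every atom, then rescales the
#' displacement field so the in-frame RMSD to the original equals the target
#' (no re-superposition). Group types are untouched.
#'
#' @param p A `pm13_pocket`.
#' @param target_rmsd Target RMSD in Angstrom (>= 0).
#' @param seed Optional integer seed for reproducibility.
#' @return List with `pocket` (the perturbed `pm13_pocket`) and `rmsd`
#'   (achieved, recomputed from the coordinates).
#' @export
perturb_to_rmsd <- function(p, target_rmsd, seed = NULL) {
  stopifnot(inherits(p, "pm13_pocket"))
  if (target_rmsd < 0) stop("input error: negative target RMSD",
                            call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  q <- p
  q$atoms <- .perturb_once(p$atoms, target_rmsd)
  achieved <- sqrt(mean(rowSums((as.matrix(q$atoms[, c("x", "y", "z")]) -
                                   as.matrix(p$atoms[, c("x", "y", "z")]))^2)))
  list(pocket = q, rmsd = achieved)
}

#' Randomly re-assign group type labels of a pocket
#'
#' A fraction of atoms, chosen without replacement, receives a uniformly
#' random *different* group type; coordinates are untouched.
#'
#' @param p A `pm13_pocket`.
#' @param fraction Fraction of atoms to relabel, in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return The relabelled `pm13_pocket`.
#' @export
relabel_types <- function(p, fraction, seed = NULL) {
  stopifnot(inherits(p, "pm13_pocket"))
  if (fraction < 0 || fraction > 1) {
    stop("input error: fraction must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(p$atoms)
  k <- floor(fraction * n)
  if (k == 0) return(p)
  idx <- sample.int(n, k)
  gt <- group_types()
  for (i in idx) {
    p$atoms$type[i] <- sample(setdiff(gt, p$atoms$type[i]), 1)
  }
  p$atoms$radius <- group_radius(p$atoms$type)
  p
}

#' Score decay under coordinate perturbation (sensitivity curve)
#'
#' Generates an ensemble of perturbed copies of a pocket with target RMSDs
#' drawn uniformly on `(0, max_rmsd]`, scores each member against the original
#' at every threshold, and returns a tidy table.
#'
#' @param p A `pm13_pocket`.
#' @param n_members Ensemble size.
#' @param max_rmsd Largest target RMSD (Angstrom).
#' @param thresholds Match thresholds (Angstrom) at which each member is
#'   scored.
#' @param seed Integer seed (required: the run is reproducible by contract).
#' @return A data.frame of class `pm13_perturbation_run` with columns
#'   `member`, `rmsd`, `threshold`, `pms_min`, `pms_max`; attributes `seed`,
#'   `n_members`, `max_rmsd`.
#' @export
sensitivity_curve <- function(p, n_members = 1000, max_rmsd = 5.0,
                              thresholds = c(0.125, 0.25, 0.5, 0.75, 1.0),
                              seed = 1L) {
  stopifnot(inherits(p, "pm13_pocket"))
  set.seed(seed)
  ref_desc <- build_descriptor(p)
  targets <- stats::runif(n_members, min = 0, max = max_rmsd)
  rows <- vector("list", n_members)
  for (m in seq_len(n_members)) {
    q <- p
    q$atoms <- .perturb_once(p$atoms, targets[m])
    achieved <- sqrt(mean(rowSums(
      (as.matrix(q$atoms[, c("x", "y", "z")]) -
         as.matrix(p$atoms[, c("x", "y", "z")]))^2)))
    dq <- build_descriptor(q)
    sc <- lapply(thresholds, function(t) compare_pockets(ref_desc, dq, t))
    rows[[m]] <- data.frame(member = m, rmsd = achieved,
                            threshold = thresholds,
                            pms_min = vapply(sc, `[[`, 1, "pms_min"),
                            pms_max = vapply(sc, `[[`, 1, "pms_max"))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  attr(out, "n_members") <- n_members
  attr(out, "max_rmsd") <- max_rmsd
  class(out) <- c("pm13_perturbation_run", class(out))
  out
}

#' Binned mean scores of a perturbation run
#'
#' Means of PMSMin per integer RMSD bin (`[0,1), [1,2), ...`) and threshold —
#' the summary used to inspect score decay.
#'
#' @param run A `pm13_perturbation_run` from [sensitivity_curve()].
#' @return data.frame with columns `threshold`, `rmsd_bin` (left edge) and
#'   `mean_pms_min`.
#' @export
bin_sensitivity <- function(run) {
  bin <- floor(run$rmsd)
  agg <- stats::aggregate(run$pms_min,
                          by = list(threshold = run$threshold,
                                    rmsd_bin = bin),
                          FUN = mean)
  names(agg)[3] <- "mean_pms_min"
  agg[order(agg$threshold, agg$rmsd_bin), ]
}
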