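# The PocketMatch_13 descriptor and score. A pocket is represented by all
# intra-site atom-pair distances, partitioned into 91 lists keyed by the
# unordered pair of ProtOr group types (13*12/2 + 13 = 91) and sorted
# non-decreasing. Two pockets are scored by aligning corresponding lists with
# a match threshold (default 0.5 A): the cumulative match count divided by
# the total distance count of the larger site is PMSMin (the default
# PM13Score), by that of the smaller site PMSMax.

#' Bin index of an unordered group-type pair
#'
#' Symmetric, bijective map from unordered pairs of the 13 group types
#' (same-type pairs included) onto 0..90.
#'
#' @param a,b Group type labels (vectorized).
#' @return Integer bin ids in `[0, 90]`.
#' @export
#' @examples
#' pair_bin_index("C3H0", "O1H0") == pair_bin_index("O1H0", "C3H0")
pair_bin_index <- function(a, b) {
  gt <- group_types()
  ia <- match(a, gt); ib <- match(b, gt)
  if (anyNA(ia) || anyNA(ib)) stop("unknown group type", call. = FALSE)
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  (lo - 1L) * 14L - (lo * (lo - 1L)) %/% 2L + (hi - lo)
}

# canonical bin labels "C3H0-C3H0", ..., in bin-index order
.bin_labels <- function() {
  gt <- group_types()
  labs <- character(91)
  for (i in seq_along(gt)) for (j in i:length(gt)) {
    labs[pair_bin_index(gt[i], gt[j]) + 1L] <- paste(gt[i], gt[j], sep = "-")
  }
  labs
}

#' Build the 91-list sorted-distance descriptor of a pocket
#'
#' Every unordered pair of pocket atoms contributes its distance to exactly
#' one bin (the unordered pair of the atoms' group types); each bin's list is
#' sorted non-decreasing. The descriptor is invariant under rigid motion.
#'
#' @param p A `pm13_pocket` with at least 3 atoms.
#' @return An object of class `pm13_descriptor`: list with `lists` (91 sorted
#'   numeric vectors, named by type pair), `n_atoms` and `n_dist`
#'   (= n_atoms(n_atoms-1)/2).
#' @export
build_descriptor <- function(p) {
  if (inherits(p, "pm13_descriptor")) return(p)
  stopifnot(inherits(p, "pm13_pocket"))
  n <- nrow(p$atoms)
  if (n < 3) stop("descriptor error: pocket has fewer than 3 atoms",
                  call. = FALSE)
  d <- as.vector(stats::dist(as.matrix(p$atoms[, c("x", "y", "z")])))
  # dist() pair order: (2,1),(3,1),...,(n,1),(3,2),...
  jj <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  ii <- unlist(lapply(seq_len(n - 1L), function(j) (j + 1L):n))
  bin <- pair_bin_index(p$atoms$type[ii], p$atoms$type[jj])
  lists <- lapply(0:90, function(b) sort(d[bin == b]))
  names(lists) <- .bin_labels()
  structure(list(lists = lists, n_atoms = n, n_dist = (n * (n - 1L)) %/% 2L),
            class = "pm13_descriptor")
}

#' @export
print.pm13_descriptor <- function(x, ...) {
  nz <- sum(lengths(x$lists) > 0)
  cat("pm13_descriptor:", x$n_atoms, "atoms,", x$n_dist, "distances in", nz,
      "of 91 bins\n")
  invisible(x)
}

#' Count matched distances between two sorted lists
#'
#' Greedy two-pointer sweep over two non-decreasing lists: the current heads
#' match if they differ by at most `threshold` (then both advance), otherwise
#' the smaller head advances. Each element is matched at most once. On sorted
#' inputs with this interval compatibility rule the greedy count equals the
#' maximum bipartite matching size (verified property, see tests).
#'
#' @param a,b Numeric vectors sorted non-decreasing.
#' @param threshold Match threshold in Angstrom.
#' @return Integer match count.
#' @export
#' @examples
#' count_matches(c(1.0, 1.3, 2.9), c(1.2, 2.8, 5.0), 0.5)  # 2
count_matches <- function(a, b, threshold = 0.5) {
  if (is.unsorted(a) || is.unsorted(b)) {
    stop("contract error: inputs to count_matches must be sorted",
         call. = FALSE)
  }
  na <- length(a); nb <- length(b)
  i <- 1L; j <- 1L; m <- 0L
  while (i <= na && j <= nb) {
    if (abs(a[i] - b[j]) <= threshold) {
      m <- m + 1L; i <- i + 1L; j <- j + 1L
    } else if (a[i] < b[j]) {
      i <- i + 1L
    } else {
      j <- j + 1L
    }
  }
  m
}

#' Compare two pockets (PocketMatch_13 score)
#'
#' Sums matched distances over the 91 corresponding list pairs and normalizes:
#' PMSMin divides by the distance count of the larger site, PMSMax by that of
#' the smaller site. PM13Score conventionally refers to PMSMin.
#'
#' @param pa,pb `pm13_pocket` or `pm13_descriptor` objects.
#' @param threshold Distance match threshold in Angstrom.
#' @return An object of class `pm13_score`: list with `pms_min`, `pms_max`,
#'   `matches`, `denominators` (larger, smaller) and `threshold`.
#' @export
compare_pockets <- function(pa, pb, threshold = 0.5) {
  da <- build_descriptor(pa); db <- build_descriptor(pb)
  if (da$n_dist == 0 || db$n_dist == 0) {
    stop("descriptor error: empty descriptor", call. = FALSE)
  }
  matches <- 0L
  for (k in seq_len(91)) {
    la <- da$lists[[k]]; lb <- db$lists[[k]]
    if (length(la) && length(lb)) {
      matches <- matches + count_matches(la, lb, threshold)
    }
  }
  larger <- max(da$n_dist, db$n_dist)
  smaller <- min(da$n_dist, db$n_dist)
  structure(list(pms_min = matches / larger, pms_max = matches / smaller,
                 matches = matches,
                 denominators = c(larger = larger, smaller = smaller),
                 threshold = threshold),
            class = "pm13_score")
}

#' @export
print.pm13_score <- function(x, ...) {
  cat(sprintf("PM13Score (threshold %.3g A): PMSMin %.3f  PMSMax %.3f  (%d matches / %d | %d)\n",
              x$threshold, x$pms_min, x$pms_max, x$matches,
              x$denominators["larger"], x$denominators["smaller"]))
  invisible(x)
}

#' All-against-all pocket comparison
#'
#' @param pockets Named list of `pm13_pocket`/`pm13_descriptor` objects, all
#'   of the same kind (whole groove, or the same sub-pocket).
#' @param threshold Match threshold in Angstrom.
#' @return An object of class `pm13_score_matrix`: list with symmetric
#'   matrices `pms_min` and `pms_max` (unit diagonal) and `threshold`.
#' @export
all_vs_all <- function(pockets, threshold = 0.5) {
  n <- length(pockets)
  if (n < 2) stop("input error: need at least 2 pockets", call. = FALSE)
  kinds <- unique(vapply(pockets, function(p) {
    if (inherits(p, "pm13_pocket")) p$kind else "descriptor"
  }, ""))
  kinds <- setdiff(kinds, "descriptor")
  if (length(kinds) > 1) {
    stop("input error: mixed pocket kinds (", paste(kinds, collapse = ", "),
         ")", call. = FALSE)
  }
  labels <- names(pockets)
  if (is.null(labels)) labels <- paste0("pocket", seq_len(n))
  desc <- lapply(pockets, build_descriptor)
  mmin <- diag(1, n); mmax <- diag(1, n)
  dimnames(mmin) <- dimnames(mmax) <- list(labels, labels)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    s <- compare_pockets(desc[[i]], desc[[j]], threshold)
    mmin[i, j] <- mmin[j, i] <- s$pms_min
    mmax[i, j] <- mmax[j, i] <- s$pms_max
  }
  structure(list(pms_min = mmin, pms_max = mmax, threshold = threshold),
            class = "pm13_score_matrix")
}

#' @export
print.pm13_score_matrix <- function(x, ...) {
  cat("pm13_score_matrix:", nrow(x$pms_min), "pockets, threshold",
      x$threshold, "A (PMSMin shown)\n")
  print(round(x$pms_min, 3))
  invisible(x)
}
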