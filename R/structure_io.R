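# Reading MHC class II-peptide complexes and standardizing them into the
# common reference frame: chain relabelling to A/B/C, renumbering of the
# alpha-1/beta-1 domains to reference positions, rigid-body superposition,
# and trimming of the peptide to the 13 harmonized positions.

#' Parse a PDB file into a raw structure
#'
#' Reads ATOM records (plus HETATM records for aliased residues such as MSE),
#' keeping heavy atoms only. For alternate locations the highest-occupancy
#' conformer is kept (ties broken by altloc label order); waters and other
#' heteroatoms are excluded.
#'
#' @param path Path to a PDB-format file.
#' @param entry_id Identifier for the structure; defaults to the file name
#'   without extension.
#' @return An object of class `raw_structure`: list with `entry_id` and
#'   `atoms`, a data.frame with columns `chain`, `resno`, `insert`, `resname`,
#'   `elety`, `x`, `y`, `z`, `o`, `b`.
#' @export
parse_structure <- function(path, entry_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("input error: no ATOM records in ", path, call. = FALSE)
  for (i in which(rec)) {
    coords <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                            substr(lines[i], 39, 46),
                                            substr(lines[i], 47, 54))))
    if (anyNA(coords) || any(!is.finite(coords))) {
      stop("format error: cannot parse coordinates at line ", i, ": ",
           lines[i], call. = FALSE)
    }
  }
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) {
                    stop("format error reading ", path, ": ",
                         conditionMessage(e), call. = FALSE)
                  })
  at <- pdb$atom
  keep_het <- at$type == "HETATM" & at$resid %in% names(.residue_aliases)
  at <- at[at$type == "ATOM" | keep_het, , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "DOD", "WAT")), , drop = FALSE]
  elesy <- toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy)))
  hyd <- elesy %in% c("H", "D") |
    (elesy == "" & grepl("^[0-9]*[HD]", trimws(at$elety)))
  at <- at[!hyd, , drop = FALSE]
  if (nrow(at) == 0) stop("input error: no protein heavy atoms in ", path,
                          call. = FALSE)
  # altloc: keep highest occupancy, ties by altloc label order
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$chain, at$resno, ifelse(is.na(at$insert), "", at$insert),
               trimws(at$elety))
  ord <- order(key, -occ, alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(match(at$chain, unique(pdb$atom$chain)), at$resno,
                 ifelse(is.na(at$insert), "", at$insert)), , drop = FALSE]
  atoms <- data.frame(chain = at$chain, resno = at$resno,
                      insert = ifelse(is.na(at$insert), "", at$insert),
                      resname = toupper(at$resid), elety = trimws(at$elety),
                      x = at$x, y = at$y, z = at$z,
                      o = ifelse(is.na(at$o), 1, at$o),
                      b = ifelse(is.na(at$b), 0, at$b),
                      stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  if (is.null(entry_id)) entry_id <- sub("\\.[^.]*$", "", basename(path))
  structure(list(entry_id = entry_id, atoms = atoms), class = "raw_structure")
}

#' @export
print.raw_structure <- function(x, ...) {
  ch <- table(x$atoms$chain)
  cat("raw_structure", x$entry_id, "-", nrow(x$atoms), "heavy atoms,",
      length(ch), "chains (", paste(names(ch), collapse = ", "), ")\n")
  invisible(x)
}

#' Declare which chains form an MHC-peptide complex
#'
#' @param alpha,beta,peptide Chain identifiers of the alpha chain, beta chain
#'   and peptide. `peptide` may be a chain shared with `alpha`/`beta` when the
#'   peptide is engineered into an MHC chain, in which case `peptide_range`
#'   must delimit it.
#' @param peptide_range Optional length-2 integer vector of author residue
#'   numbers delimiting the peptide within its chain.
#' @return An object of class `complex_spec`.
#' @export
complex_spec <- function(alpha, beta, peptide, peptide_range = NULL) {
  if (alpha == beta) stop("alpha and beta chains must differ", call. = FALSE)
  if (peptide %in% c(alpha, beta) && is.null(peptide_range)) {
    stop("peptide shares a chain with the MHC; give peptide_range",
         call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, peptide = peptide,
                 peptide_range = peptide_range), class = "complex_spec")
}

# per-chain residue table, in file order
.chain_residues <- function(raw, chain, range = NULL, exclude_range = NULL) {
  at <- raw$atoms[raw$atoms$chain == chain, , drop = FALSE]
  if (!is.null(range)) {
    at <- at[at$resno >= range[1] & at$resno <= range[2], , drop = FALSE]
  }
  if (!is.null(exclude_range)) {
    at <- at[!(at$resno >= exclude_range[1] & at$resno <= exclude_range[2]),
             , drop = FALSE]
  }
  if (nrow(at) == 0) return(NULL)
  key <- paste(at$resno, at$insert)
  idx <- !duplicated(key)
  data.frame(resno = at$resno[idx], insert = at$insert[idx],
             resname = at$resname[idx], stringsAsFactors = FALSE)
}

.chain_sequence <- function(res) {
  if (is.null(res)) return("")
  paste(bio3d::aa321(res$resname), collapse = "")
}

#' Identify alpha/beta/peptide complexes in a structure
#'
#' When `spec` is supplied it is validated against the structure and returned.
#' Otherwise a heuristic is applied: chains of 70-120 residues are matched
#' against the reference alpha-1 and beta-1 profiles by global sequence
#' alignment and classified by the higher identity; chains of 9-25 residues
#' are peptide candidates. Candidate alpha chains are paired with the
#' spatially nearest unused beta chain and peptide, so a file with several
#' copies of the complex yields several specs.
#'
#' @param raw A `raw_structure` from [parse_structure()].
#' @param spec Optional [complex_spec()] override.
#' @param ref Reference frame, see [reference_frame()].
#' @return List of `complex_spec` objects.
#' @export
identify_complexes <- function(raw, spec = NULL, ref = reference_frame()) {
  stopifnot(inherits(raw, "raw_structure"))
  chains <- unique(raw$atoms$chain)
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "complex_spec"))
    miss <- setdiff(c(spec$alpha, spec$beta, spec$peptide), chains)
    if (length(miss)) stop("chain(s) not in structure: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    return(list(spec))
  }
  if (length(chains) < 2) {
    stop("detection error: fewer than two chains; pass an explicit ",
         "complex_spec", call. = FALSE)
  }
  res_by_chain <- lapply(chains, function(ch) .chain_residues(raw, ch))
  names(res_by_chain) <- chains
  nres <- vapply(res_by_chain, nrow, 1L)
  dom <- chains[nres >= 70 & nres <= 120]
  pep <- chains[nres >= 9 & nres <= 25]
  ident <- function(q, r) {
    # low identity against the wrong profile is expected, not a warning
    m <- suppressWarnings(align_domain_sequence(q, r))
    attr(m, "identity")
  }
  cls <- lapply(dom, function(ch) {
    s <- .chain_sequence(res_by_chain[[ch]])
    c(alpha = ident(s, ref$alpha_seq), beta = ident(s, ref$beta_seq))
  })
  names(cls) <- dom
  alphas <- dom[vapply(cls, function(v) v["alpha"] >= v["beta"], TRUE)]
  betas <- setdiff(dom, alphas)
  if (!length(alphas) || !length(betas) || !length(pep)) {
    stop("detection error: could not find an alpha/beta/peptide triple; ",
         "pass an explicit complex_spec", call. = FALSE)
  }
  cent <- function(ch) colMeans(as.matrix(
    raw$atoms[raw$atoms$chain == ch, c("x", "y", "z")]))
  out <- list()
  used_b <- character(0); used_p <- character(0)
  for (a in alphas) {
    bs <- setdiff(betas, used_b); ps <- setdiff(pep, used_p)
    if (!length(bs) || !length(ps)) break
    ca <- cent(a)
    b <- bs[which.min(vapply(bs, function(ch) sum((cent(ch) - ca)^2), 1))]
    p <- ps[which.min(vapply(ps, function(ch) sum((cent(ch) - ca)^2), 1))]
    used_b <- c(used_b, b); used_p <- c(used_p, p)
    out[[length(out) + 1L]] <- complex_spec(a, b, p)
  }
  if (!length(out)) {
    stop("detection error: could not assemble a complex; pass an explicit ",
         "complex_spec", call. = FALSE)
  }
  out
}

#' Globally align a query domain sequence to a reference profile
#'
#' Needleman-Wunsch global alignment (default scoring: match +1, mismatch 0,
#' gap -1) producing a strictly increasing mapping from query residues to
#' reference positions.
#'
#' @param query,ref One-letter amino-acid strings; query must have >= 30
#'   residues.
#' @param match,mismatch,gap Alignment scores (gap is per gapped position).
#' @return Integer vector of length `nchar(query)` giving the 1-based index of
#'   the reference residue each query residue is aligned to (NA when aligned
#'   to a gap), with attributes `identity` (fraction of aligned columns that
#'   are identical) and `low_identity` (TRUE below 30% identity).
#' @export
align_domain_sequence <- function(query, ref, match = 1, mismatch = 0,
                                  gap = -1) {
  if (nchar(query) < 30) {
    stop("precondition error: query shorter than 30 residues", call. = FALSE)
  }
  letters_all <- sort(unique(strsplit(paste0(query, ref), "")[[1]]))
  sm <- matrix(mismatch, length(letters_all), length(letters_all),
               dimnames = list(letters_all, letters_all))
  diag(sm) <- match
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::BString(query), Biostrings::BString(ref),
    substitutionMatrix = sm, gapOpening = 0, gapExtension = abs(gap),
    type = "global")
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  mapping <- rep(NA_integer_, nchar(query))
  qi <- 0L; ri <- 0L; naligned <- 0L; nident <- 0L
  for (k in seq_along(ap)) {
    qg <- ap[k] == "-"; rg <- as[k] == "-"
    if (!qg) qi <- qi + 1L
    if (!rg) ri <- ri + 1L
    if (!qg && !rg) {
      mapping[qi] <- ri
      naligned <- naligned + 1L
      if (ap[k] == as[k]) nident <- nident + 1L
    }
  }
  identity <- if (naligned > 0) nident / naligned else 0
  attr(mapping, "identity") <- identity
  attr(mapping, "low_identity") <- identity < 0.3
  if (identity < 0.3) {
    warning("alignment identity below 30% (", round(100 * identity, 1),
            "%); proceeding", call. = FALSE)
  }
  mapping
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of paired point sets via singular value
#' decomposition, constrained to a proper rotation (determinant +1).
#'
#' @param mobile,target Numeric matrices (n x 3) of paired coordinates,
#'   n >= 3.
#' @return List with `rotation` (3 x 3, det +1), `translation` (length 3) and
#'   `rmsd` (Angstrom). The transform maps `mobile %*% rotation + translation`
#'   onto `target`; apply it with [apply_transform()].
#' @export
kabsch_superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (ncol(mobile) != 3 || ncol(target) != 3) {
    stop("input error: coordinate matrices must have 3 columns", call. = FALSE)
  }
  if (nrow(mobile) != nrow(target)) {
    stop("input error: point lists differ in length", call. = FALSE)
  }
  if (nrow(mobile) < 3) stop("input error: need at least 3 points",
                             call. = FALSE)
  cm <- colMeans(mobile); ct <- colMeans(target)
  A <- sweep(mobile, 2, cm); B <- sweep(target, 2, ct)
  H <- crossprod(A, B)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  tr <- ct - as.vector(cm %*% R)
  fitted <- sweep(A %*% R, 2, ct, "+")
  rmsd <- sqrt(mean(rowSums((fitted - target)^2)))
  list(rotation = R, translation = tr, rmsd = rmsd)
}

#' Apply a rigid-body transform to coordinates
#'
#' @param xyz Numeric matrix (n x 3).
#' @param transform List with `rotation` and `translation`, as returned by
#'   [kabsch_superpose()].
#' @return Transformed (n x 3) matrix.
#' @export
apply_transform <- function(xyz, transform) {
  sweep(as.matrix(xyz) %*% transform$rotation, 2, transform$translation, "+")
}

# order-consistent injective assignment of peptide residues to reference
# peptide positions: maximize assignments, then minimize total Ca distance;
# assignments beyond `cutoff` Angstrom are not allowed.
.assign_peptide <- function(pep_ca, ref_ca, cutoff = 6.0) {
  m <- nrow(pep_ca); n <- nrow(ref_ca)
  if (m == 0) return(integer(0))
  D <- sqrt(pmax(outer(rowSums(pep_ca^2), rep(1, n)) +
                   outer(rep(1, m), rowSums(ref_ca^2)) -
                   2 * pep_ca %*% t(ref_ca), 0))
  BIG <- 1e6
  F <- matrix(0, m + 1, n + 1)
  P <- matrix(0L, m + 1, n + 1)  # 1 diag(assign), 2 up(skip residue), 3 left
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      up <- F[i, j + 1]; left <- F[i + 1, j]
      best <- up; move <- 2L
      if (left > best) { best <- left; move <- 3L }
      if (D[i, j] <= cutoff) {
        dg <- F[i, j] + BIG - D[i, j]
        if (dg > best) { best <- dg; move <- 1L }
      }
      F[i + 1, j + 1] <- best; P[i + 1, j + 1] <- move
    }
  }
  assign <- rep(NA_integer_, m)
  i <- m + 1L; j <- n + 1L
  while (i > 1L && j > 1L) {
    mv <- P[i, j]
    if (mv == 1L) { assign[i - 1L] <- j - 1L; i <- i - 1L; j <- j - 1L }
    else if (mv == 2L) i <- i - 1L
    else j <- j - 1L
  }
  assign
}

.domain_atoms <- function(raw, chain, mapping, res, ref_dom, new_chain,
                          exclude_range = NULL) {
  keep <- which(!is.na(mapping))
  out <- list()
  at <- raw$atoms[raw$atoms$chain == chain, , drop = FALSE]
  if (!is.null(exclude_range)) {
    at <- at[!(at$resno >= exclude_range[1] & at$resno <= exclude_range[2]),
             , drop = FALSE]
  }
  for (k in keep) {
    sel <- at$resno == res$resno[k] & at$insert == res$insert[k]
    a <- at[sel, , drop = FALSE]
    a$chain <- new_chain
    a$resno <- ref_dom$pos[mapping[k]]
    a$insert <- ""
    out[[length(out) + 1L]] <- a
  }
  do.call(rbind, out)
}

#' Standardize a complex into the reference frame
#'
#' Renumbers the alpha-1 and beta-1 domains to reference positions (5-78 and
#' 5-91) by global sequence alignment, superposes the complex onto the
#' reference over the mapped Calpha pairs of both domains jointly, assigns
#' peptide residues to the 13 reference peptide positions (308-320) by
#' nearest reference Calpha under an order-consistent injective assignment,
#' and relabels chains to A/B/C. Peptide residues that cannot be assigned are
#' removed.
#'
#' @param raw A `raw_structure`.
#' @param spec A [complex_spec()] naming the chains.
#' @param ref Reference frame.
#' @param peptide_cutoff Maximum Calpha distance (Angstrom) for a peptide
#'   residue to claim a reference position.
#' @param gap Alignment gap score passed to [align_domain_sequence()].
#' @return An object of class `standard_complex`: list with `atoms`
#'   (data.frame as in `raw_structure`, chains exactly A/B/C, reference
#'   numbering), `transform` (rotation/translation/rmsd of the superposition)
#'   and `source` (entry id and original chain ids).
#' @export
standardize_complex <- function(raw, spec, ref = reference_frame(),
                                peptide_cutoff = 6.0, gap = -1) {
  stopifnot(inherits(raw, "raw_structure"), inherits(spec, "complex_spec"))
  dom_map <- function(chain, ref_dom, ref_seq, exclude_range = NULL) {
    res <- .chain_residues(raw, chain, exclude_range = exclude_range)
    if (is.null(res)) stop("standardization error: chain ", chain, " empty",
                           call. = FALSE)
    mapping <- align_domain_sequence(.chain_sequence(res), ref_seq, gap = gap)
    if (sum(!is.na(mapping)) < 0.5 * nrow(ref_dom)) {
      stop("standardization error: <50% of reference positions mapped for ",
           "chain ", chain, call. = FALSE)
    }
    list(res = res, mapping = mapping)
  }
  pr <- spec$peptide_range
  a_ex <- if (!is.null(pr) && spec$peptide == spec$alpha) pr else NULL
  b_ex <- if (!is.null(pr) && spec$peptide == spec$beta) pr else NULL
  am <- dom_map(spec$alpha, ref$alpha, ref$alpha_seq, a_ex)
  bm <- dom_map(spec$beta, ref$beta, ref$beta_seq, b_ex)

  ca_pairs <- function(chain, dm, ref_dom, exclude_range = NULL) {
    at <- raw$atoms[raw$atoms$chain == chain, , drop = FALSE]
    if (!is.null(exclude_range)) {
      at <- at[!(at$resno >= exclude_range[1] & at$resno <= exclude_range[2]),
               , drop = FALSE]
    }
    mob <- NULL; tar <- NULL
    for (k in which(!is.na(dm$mapping))) {
      sel <- at$resno == dm$res$resno[k] & at$insert == dm$res$insert[k] &
        at$elety == "CA"
      if (any(sel)) {
        mob <- rbind(mob, as.matrix(at[which(sel)[1], c("x", "y", "z")]))
        ri <- dm$mapping[k]
        tar <- rbind(tar, as.matrix(ref_dom[ri, c("x", "y", "z")]))
      }
    }
    list(mob = mob, tar = tar)
  }
  pa <- ca_pairs(spec$alpha, am, ref$alpha, a_ex)
  pb <- ca_pairs(spec$beta, bm, ref$beta, b_ex)
  tf <- kabsch_superpose(rbind(pa$mob, pb$mob), rbind(pa$tar, pb$tar))

  atoms_a <- .domain_atoms(raw, spec$alpha, am$mapping, am$res, ref$alpha,
                           "A", a_ex)
  atoms_b <- .domain_atoms(raw, spec$beta, bm$mapping, bm$res, ref$beta,
                           "B", b_ex)

  pep_res <- .chain_residues(raw, spec$peptide, range = pr)
  if (is.null(pep_res)) stop("standardization error: peptide chain empty",
                             call. = FALSE)
  pat <- raw$atoms[raw$atoms$chain == spec$peptide, , drop = FALSE]
  if (!is.null(pr)) pat <- pat[pat$resno >= pr[1] & pat$resno <= pr[2], ,
                               drop = FALSE]
  pep_ca <- matrix(NA_real_, nrow(pep_res), 3)
  for (k in seq_len(nrow(pep_res))) {
    sel <- pat$resno == pep_res$resno[k] & pat$insert == pep_res$insert[k] &
      pat$elety == "CA"
    if (any(sel)) pep_ca[k, ] <- as.numeric(pat[which(sel)[1],
                                                c("x", "y", "z")])
  }
  ok <- which(stats::complete.cases(pep_ca))
  assign <- rep(NA_integer_, nrow(pep_res))
  if (length(ok)) {
    assign[ok] <- .assign_peptide(apply_transform(pep_ca[ok, , drop = FALSE],
                                                  tf),
                                  as.matrix(ref$peptide[, c("x", "y", "z")]),
                                  cutoff = peptide_cutoff)
  }
  if (all(is.na(assign))) {
    stop("standardization error: no peptide residue could be assigned to a ",
         "reference position", call. = FALSE)
  }
  atoms_c <- .domain_atoms(raw, spec$peptide, assign, pep_res, ref$peptide,
                           "C")

  atoms <- rbind(atoms_a, atoms_b, atoms_c)
  atoms[, c("x", "y", "z")] <- apply_transform(
    as.matrix(atoms[, c("x", "y", "z")]), tf)
  atoms <- atoms[order(match(atoms$chain, c("A", "B", "C")), atoms$resno), ,
                 drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, transform = tf,
                 source = list(entry_id = raw$entry_id,
                               chains = c(spec$alpha, spec$beta,
                                          spec$peptide))),
            class = "standard_complex")
}

#' @export
print.standard_complex <- function(x, ...) {
  np <- length(unique(x$atoms$resno[x$atoms$chain == "C"]))
  cat("standard_complex from", x$source$entry_id, "(chains",
      paste(x$source$chains, collapse = ""), ")-",
      nrow(x$atoms), "atoms,", np, "peptide residues\n")
  invisible(x)
}

#' Write a standardized complex as a PDB file
#'
#' Chains A/B/C with reference numbering and transformed coordinates;
#' re-reading with [parse_structure()] reproduces the complex (coordinates to
#' 3 decimals).
#'
#' @param sc A `standard_complex`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_standard_pdb <- function(sc, path) {
  stopifnot(inherits(sc, "standard_complex"))
  a <- sc$atoms
  if (!any(a$chain == "C")) {
    stop("contract error: refusing to write a complex with an empty peptide",
         call. = FALSE)
  }
  bio3d::write.pdb(file = path,
                   xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, chain = a$chain, resid = a$resname,
                   elety = a$elety, o = a$o, b = a$b)
  invisible(path)
}
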