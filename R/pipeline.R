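# End-to-end orchestration: prepare (standardize) -> pockets -> all-vs-all
# score matrices -> cladograms and histograms. Deterministic given its
# configuration, which is echoed into the output directory.

#' Run the full groove-comparison pipeline
#'
#' For each input PDB: parse, identify complexes (with optional per-entry
#' chain overrides), standardize into the reference frame, write the
#' standardized PDB, and extract the whole groove plus the five sub-pockets.
#' For every pocket kind with at least two extractable pockets, an
#' all-against-all PMSMin/PMSMax matrix, a neighbour-joining Newick tree
#' (3+ pockets) and a ten-bin score histogram are written. The effective
#' configuration is echoed as JSON.
#'
#' @param inputs Character vector of PDB file paths.
#' @param out_dir Output directory (created if absent).
#' @param chain_specs Optional named list (by entry id) of [complex_spec()]
#'   overrides.
#' @param threshold Match threshold (Angstrom).
#' @param probe,n_points,epsilon SASA / extraction parameters, see
#'   [groove_atoms()].
#' @param lenient If TRUE, per-entry failures are logged and skipped; if
#'   FALSE they abort the run.
#' @return Invisibly, a list with `pockets`, `matrices`, `trees`, `log` and
#'   `out_dir`.
#' @export
run_pipeline <- function(inputs, out_dir, chain_specs = NULL, threshold = 0.5,
                         probe = 1.4, n_points = 960, epsilon = 0.1,
                         lenient = FALSE) {
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in)) {
    stop("config error: missing input path(s): ",
         paste(missing_in, collapse = ", "), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  std_dir <- file.path(out_dir, "standardized")
  pk_dir <- file.path(out_dir, "pockets")
  dir.create(std_dir, showWarnings = FALSE)
  dir.create(pk_dir, showWarnings = FALSE)
  log <- character(0)
  note <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message(msg)
  }
  cfg <- list(inputs = inputs, out_dir = out_dir, threshold = threshold,
              probe = probe, n_points = n_points, epsilon = epsilon,
              lenient = lenient,
              package_version = as.character(utils::packageVersion("pm13")))
  jsonlite::write_json(cfg, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)

  kinds <- c("whole", "P1", "P4", "P6", "P7", "P9")
  pockets <- stats::setNames(lapply(kinds, function(k) list()), kinds)
  for (path in inputs) {
    res <- tryCatch({
      raw <- parse_structure(path)
      spec <- if (!is.null(chain_specs)) chain_specs[[raw$entry_id]] else NULL
      specs <- identify_complexes(raw, spec = spec)
      for (si in seq_along(specs)) {
        sc <- standardize_complex(raw, specs[[si]])
        label <- paste0(raw$entry_id, "-",
                        paste(specs[[si]][c("alpha", "beta", "peptide")],
                              collapse = ""))
        write_standard_pdb(sc, file.path(std_dir, paste0(label, ".pdb")))
        pks <- extract_pockets(sc, epsilon = epsilon, probe = probe,
                               n_points = n_points)
        for (k in kinds) {
          if (!is.null(pks[[k]])) {
            write_pocket(pks[[k]], file.path(pk_dir,
                                             paste0(label, "_", k, ".tsv")))
            pockets[[k]][[label]] <- pks[[k]]
          }
        }
        note("standardized ", label, ": pockets ",
             paste(names(Filter(Negate(is.null), pks)), collapse = ","))
      }
      TRUE
    }, error = function(e) {
      if (!lenient) stop(e)
      note("skipped ", path, ": ", conditionMessage(e))
      FALSE
    })
    invisible(res)
  }

  matrices <- list(); trees <- list()
  for (k in kinds) {
    pk <- pockets[[k]]
    if (length(pk) < 2) next
    m <- all_vs_all(pk, threshold = threshold)
    matrices[[k]] <- m
    utils::write.table(m$pms_min,
                       file.path(out_dir, paste0("scores_", k, "_pmsmin.tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(m$pms_max,
                       file.path(out_dir, paste0("scores_", k, "_pmsmax.tsv")),
                       sep = "\t", quote = FALSE, col.names = NA)
    hist <- score_histogram(pairwise_scores(m))
    utils::write.table(data.frame(bin = names(hist), count = hist),
                       file.path(out_dir, paste0("hist_", k, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (length(pk) >= 3) {
      tr <- neighbor_join(to_distance_matrix(m))
      trees[[k]] <- tr
      to_newick(tr, file.path(out_dir, paste0("tree_", k, ".nwk")))
    }
    note("scored ", k, ": ", length(pk), " pockets")
  }
  writeLines(log, file.path(out_dir, "run.log"))
  invisible(list(pockets = pockets, matrices = matrices, trees = trees,
                 log = log, out_dir = out_dir))
}
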