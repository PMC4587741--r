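# Assembly parameter sweep: p-value threshold arithmetic, the staged
# 3 + 2 sweep over thresholds and minimum molecule lengths, and candidate
# assembly scoring. This plans and ranks runs of the external consensus-map
# assembler; it never invokes it.

#' Assembly sweep settings
#'
#' The default p-value threshold scales inversely with estimated genome
#' length: `default = threshold_numerator / genome_length_mb`. The default
#' calibration (`1e-6` per Mb) reproduces the threshold triple
#' (5e-08, 5e-09, 5e-10) used for a 200 Mb genome; the numerator is
#' exposed because published formulations of the constant disagree.
#'
#' @param genome_length_mb estimated haploid genome length in Mb (> 0).
#' @param threshold_numerator numerator of the default-threshold formula.
#' @param minlen_default default minimum molecule length (bp), 150 kb.
#' @param minlen_variants the relaxed/strict minimum-length variants (bp),
#'   100 and 180 kb.
#' @return an object of class `sweep_config`.
#' @export
sweep_config <- function(genome_length_mb, threshold_numerator = 1e-6,
                         minlen_default = 150000,
                         minlen_variants = c(100000, 180000)) {
  if (!is.finite(genome_length_mb) || genome_length_mb <= 0)
    stop("genome length (Mb) must be > 0")
  stopifnot(threshold_numerator > 0)
  structure(list(genome_length_mb = genome_length_mb,
                 threshold_numerator = threshold_numerator,
                 minlen_default = minlen_default,
                 minlen_variants = minlen_variants),
            class = "sweep_config")
}

#' Compute the relaxed/default/strict p-value threshold triple
#'
#' `default = numerator / genome length (Mb)`, `strict = default / 10`,
#' `relaxed = default * 10`.
#'
#' @param config a [sweep_config()], or a bare genome length in Mb.
#' @return list of class `threshold_triple` with elements `relaxed`,
#'   `default`, `strict`.
#' @export
compute_thresholds <- function(config) {
  if (is.numeric(config)) config <- sweep_config(config)
  default <- config$threshold_numerator / config$genome_length_mb
  structure(list(relaxed = default * 10, default = default,
                 strict = default / 10),
            class = "threshold_triple")
}

#' @export
print.threshold_triple <- function(x, ...) {
  cat(sprintf("<threshold_triple relaxed=%g default=%g strict=%g>\n",
              x$relaxed, x$default, x$strict))
  invisible(x)
}

#' Plan the staged assembly sweep
#'
#' The first round runs three assemblies (relaxed/default/strict
#' threshold) at the default minimum molecule length; the minlen round
#' runs the best first-round threshold at the two minimum-length variants.
#' Across both stages at most 3 x 3 = 9 distinct configurations exist.
#'
#' @param config a [sweep_config()].
#' @param stage `"first-round"` or `"minlen-round"`.
#' @param best_first_round_T the selected threshold (required for the
#'   minlen round).
#' @return list of run configs, each a list with `name`, `p_value_threshold`,
#'   `min_molecule_length`, `stage`.
#' @export
plan_sweep <- function(config, stage = c("first-round", "minlen-round"),
                       best_first_round_T = NULL) {
  stage <- match.arg(stage)
  if (stage == "first-round") {
    tt <- compute_thresholds(config)
    mapply(function(nm, t) list(name = nm, p_value_threshold = t,
                                min_molecule_length = config$minlen_default,
                                stage = stage),
           c("relaxed_T", "default_T", "strict_T"),
           c(tt$relaxed, tt$default, tt$strict),
           SIMPLIFY = FALSE, USE.NAMES = TRUE)
  } else {
    if (is.null(best_first_round_T))
      stop("minlen-round requires the best first-round threshold")
    mapply(function(nm, ml) list(name = nm,
                                 p_value_threshold = best_first_round_T,
                                 min_molecule_length = ml, stage = stage),
           c("relaxed_minlen", "strict_minlen"),
           sort(config$minlen_variants),
           SIMPLIFY = FALSE, USE.NAMES = TRUE)
  }
}

#' Write sweep run configs as declarative files
#'
#' One `key: value` text file per assembly run, naming the threshold,
#' minimum molecule length and stage; invoking the external assembler with
#' them is the user's step.
#'
#' @param plans list from [plan_sweep()].
#' @param dir output directory (created if needed).
#' @return character vector of file paths, invisibly.
#' @export
write_run_configs <- function(plans, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(plans, function(p) {
    path <- file.path(dir, paste0(p$name, ".cfg"))
    writeLines(c(sprintf("name: %s", p$name),
                 sprintf("p_value_threshold: %g", p$p_value_threshold),
                 sprintf("min_molecule_length: %d",
                         as.integer(p$min_molecule_length)),
                 sprintf("stage: %s", p$stage)), path)
    path
  }, "")
  invisible(paths)
}

#' Score one candidate assembly
#'
#' A good consensus-map assembly has cumulative length close to the
#' estimated genome length and aligns to the in silico maps with minimal
#' redundancy (total aligned length close to non-redundant breadth).
#'
#' @param stats one-row data.frame from [cmap_stats()] for the candidate.
#' @param coverage an `alignment_coverage` of the candidate against the
#'   common in silico map set.
#' @param genome_length_bp estimated haploid genome length (bp).
#' @return list of class `assembly_score`: `cumulative_length`,
#'   `genome_length_delta`, `redundancy`, `redundancy_ratio`, `delta_ratio`.
#' @export
score_assembly <- function(stats, coverage, genome_length_bp) {
  delta <- abs(stats$cumulative_length - genome_length_bp)
  rr <- if (coverage$breadth > 0) coverage$redundancy / coverage$breadth
        else Inf
  structure(list(cumulative_length = stats$cumulative_length,
                 genome_length_delta = delta,
                 redundancy = coverage$redundancy,
                 redundancy_ratio = rr,
                 delta_ratio = delta / genome_length_bp),
            class = "assembly_score")
}

#' Rank candidate assemblies
#'
#' Orders candidates lexicographically ascending on the rank key. Both
#' orderings of the two criteria are available since neither has published
#' precedence; ties preserve input order, and the full table is returned so
#' a human can override the suggestion.
#'
#' @param scores named list of `assembly_score` objects.
#' @param order `"redundancy-first"` (default) or `"delta-first"`.
#' @return data.frame ordered best-first, with columns `candidate`,
#'   `cumulative_length`, `genome_length_delta`, `redundancy`,
#'   `redundancy_ratio`, `delta_ratio`, `rank`.
#' @export
rank_assemblies <- function(scores, order = c("redundancy-first",
                                              "delta-first")) {
  order <- match.arg(order)
  stopifnot(length(scores) >= 1L)
  nms <- names(scores) %||% paste0("candidate_", seq_along(scores))
  tab <- do.call(rbind, lapply(seq_along(scores), function(i) {
    s <- scores[[i]]
    data.frame(candidate = nms[i], cumulative_length = s$cumulative_length,
               genome_length_delta = s$genome_length_delta,
               redundancy = s$redundancy,
               redundancy_ratio = s$redundancy_ratio,
               delta_ratio = s$delta_ratio, stringsAsFactors = FALSE)
  }))
  o <- if (order == "redundancy-first")
    order(tab$redundancy_ratio, tab$delta_ratio)
  else order(tab$delta_ratio, tab$redundancy_ratio)
  tab <- tab[o, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab
}
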