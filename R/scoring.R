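#' Filter CNV calls by size, QC status, and chromosome
#'
#' Standard pre-scoring filter: keeps autosomal calls that passed QC and
#' span at least `min_size_bp` (length is `end - start` under the 0-based
#' half-open convention; a call of exactly the threshold length is kept).
#' chrY and mitochondrial calls are always dropped; chrX calls are dropped
#' unless `include_chrX = TRUE` (the X-chromosome sensitivity toggle).
#'
#' @param calls Tibble of CNV calls (`sample_id`, `chrom`, `start`, `end`,
#'   `type`, `platform`, `qc_pass`; a missing `qc_pass` column is treated
#'   as all-pass).
#' @param min_size_bp Minimum call length in base pairs (default 50 kb).
#' @param include_chrX Keep chrX calls?
#' @return The filtered calls tibble.
#' @export
filter_cnvs <- function(calls, min_size_bp = 5e4, include_chrX = FALSE) {
  if (min_size_bp <= 0) {
    abort("`min_size_bp` must be positive.", class = "cnvrisk_config_error")
  }
  bad <- which(calls$start >= calls$end)
  if (length(bad) > 0L) {
    abort(paste0("Malformed coordinates (start >= end) in call(s): ",
                 paste(sprintf("%s %s:%s-%s", calls$sample_id[bad],
                               calls$chrom[bad], calls$start[bad],
                               calls$end[bad])[seq_len(min(5, length(bad)))],
                       collapse = "; ")),
          class = "cnvrisk_validation_error")
  }
  qc <- if ("qc_pass" %in% names(calls)) calls$qc_pass else TRUE
  drop_chrom <- c("chrY", "chrM", "chrMT")
  if (!include_chrX) drop_chrom <- c(drop_chrom, "chrX")
  calls[qc &
          (calls$end - calls$start) >= min_size_bp &
          !(calls$chrom %in% drop_chrom), , drop = FALSE]
}

#' Genes encompassed by a single CNV
#'
#' Returns the genes a CNV call affects under the chosen overlap rule. The
#' default (`"containment"`) requires the gene to lie fully within the CNV
#' — the convention of cumulative CNV risk-score models, where a partially
#' overlapped gene's dosage is not unambiguously altered. `"any"` counts
#' any base-pair overlap and is offered for sensitivity analyses.
#'
#' @param cnv A single CNV call (one-row tibble or named list with `chrom`,
#'   `start`, `end`).
#' @param genes Gene annotation tibble.
#' @param rule `"containment"` (default) or `"any"`.
#' @return The subset of `genes` affected (possibly zero rows; a CNV on a
#'   chromosome absent from the gene table yields zero rows).
#' @export
genes_in_cnv <- function(cnv, genes, rule = c("containment", "any")) {
  rule <- match.arg(rule)
  hit <- genes$chrom == cnv$chrom &
    if (rule == "containment") {
      genes$start >= cnv$start & genes$end <= cnv$end
    } else {
      genes$start < cnv$end & genes$end > cnv$start
    }
  genes[hit, , drop = FALSE]
}

#' Per-sample cumulative CNV risk scores under every annotation scheme
#'
#' For each sample and copy state (deletion/duplication) computes the
#' cumulative burden under each scheme: total size in bp, number of genes
#' encompassed, and the sums of pLI, 1/LOEUF, and the state-matched dosage
#' sensitivity (pHI over deleted genes, pTS over duplicated genes).
#' Overlapping same-state calls within a sample are merged before scoring;
#' exact duplicate records are dropped with a warning. Samples listed in
#' `samples` but carrying no calls receive an all-zero profile (they stay
#' in the cohort). Interval containment runs on a GenomicRanges overlap
#' engine; the brute-force equivalent is used as a test oracle.
#'
#' @param calls Filtered CNV calls ([filter_cnvs()]).
#' @param genes Gene annotation tibble with `pHI`, `pTS`, `pLI`, `LOEUF`.
#' @param samples Character vector of cohort sample ids; defaults to the
#'   samples present in `calls`.
#' @param rule Gene-overlap rule, see [genes_in_cnv()].
#' @return A tibble, one row per sample: `sample_id`, `del_total_size`,
#'   `del_n_genes`, `del_sum_pLI`, `del_sum_invLOEUF`, `del_sum_pHI`, and
#'   the `dup_*` counterparts with `dup_sum_pTS`.
#' @export
score_samples <- function(calls, genes, samples = NULL,
                          rule = c("containment", "any")) {
  rule <- match.arg(rule)
  samples <- samples %||% unique(calls$sample_id)
  zero <- tibble(sample_id = samples)
  for (col in .profile_cols) zero[[col]] <- 0
  if (nrow(calls) == 0L) {
    return(zero)
  }

  key_cols <- c("sample_id", "chrom", "start", "end", "type")
  dup <- duplicated(calls[key_cols])
  if (any(dup)) {
    warn(paste("Dropping", sum(dup), "duplicate CNV record(s)."))
    calls <- calls[!dup, , drop = FALSE]
  }
  merged <- merge_same_state_calls(calls)

  cnv_gr <- GenomicRanges::GRanges(
    merged$chrom, IRanges::IRanges(merged$start + 1, merged$end)
  )
  gene_gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1, genes$end)
  )
  ov_type <- if (rule == "containment") "within" else "any"
  hits <- GenomicRanges::findOverlaps(gene_gr, cnv_gr, type = ov_type)

  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)

  # accumulate per (sample, state) with rowsum; one pass for all schemes
  out <- zero
  accumulate <- function(state, dosage_col, target_prefix, target_dosage) {
    in_state <- merged$type == state
    state_rows <- which(in_state)
    hit_sel <- sh %in% state_rows
    idx_call <- sh[hit_sel]
    idx_gene <- qh[hit_sel]
    key <- merged$sample_id[idx_call]
    sums <- rowsum(
      cbind(n = rep(1, length(idx_gene)), pLI = genes$pLI[idx_gene],
            invLOEUF = 1 / genes$LOEUF[idx_gene],
            dosage = genes[[dosage_col]][idx_gene]),
      key
    )
    sizes <- rowsum(merged$end[state_rows] - merged$start[state_rows],
                    merged$sample_id[state_rows])
    i <- match(out$sample_id, rownames(sizes))
    out[[paste0(target_prefix, "total_size")]] <<-
      if_else(is.na(i), 0, unname(sizes[i, 1]))
    j <- match(out$sample_id, rownames(sums))
    fill <- function(col) if_else(is.na(j), 0, unname(sums[j, col]))
    out[[paste0(target_prefix, "n_genes")]] <<- fill("n")
    out[[paste0(target_prefix, "sum_pLI")]] <<- fill("pLI")
    out[[paste0(target_prefix, "sum_invLOEUF")]] <<- fill("invLOEUF")
    out[[target_dosage]] <<- fill("dosage")
  }
  accumulate("deletion", "pHI", "del_", "del_sum_pHI")
  accumulate("duplication", "pTS", "dup_", "dup_sum_pTS")
  out[c("sample_id", .profile_cols)]
}

# Merge overlapping (or abutting) same-sample, same-state calls with a
# vectorized sorted run scan (union of intervals per sample/state/chrom).
merge_same_state_calls <- function(calls) {
  key <- paste(calls$sample_id, calls$type, calls$chrom, sep = "\r")
  g <- as.integer(factor(key))
  ord <- order(g, calls$start)
  g <- g[ord]
  start <- calls$start[ord]
  end <- calls$end[ord]
  # cummax of end within group, computed globally via a per-group offset
  big <- max(end) + 1
  cm <- cummax(end + as.numeric(g) * big) - as.numeric(g) * big
  prev_cm <- c(-Inf, cm[-length(cm)])
  new_run <- c(TRUE, g[-1] != g[-length(g)]) | start > prev_cm
  run <- cumsum(new_run)
  first <- which(new_run)
  last <- c(first[-1] - 1L, length(run))
  parts <- stringr::str_split_fixed(key[ord][first], "\r", 3)
  tibble(
    sample_id = parts[, 1],
    type = parts[, 2],
    chrom = parts[, 3],
    start = start[first],
    end = cm[last]
  )
}

#' Add log and indicator transforms to a risk-score profile
#'
#' Cumulative scores are zero for most individuals and right-skewed, so
#' two standard transforms accompany the raw sums: `log1p` (natural log of
#' 1 + sum, which maps zero to zero and preserves rank order) applied to
#' the pLI and 1/LOEUF sums, and binary indicators of any dosage-sensitive
#' gene content (`del_pHI_gt0`, `dup_pTS_gt0`).
#'
#' @param profile Output of [score_samples()].
#' @return The profile with `del_log_pLI`, `del_log_invLOEUF`,
#'   `dup_log_pLI`, `dup_log_invLOEUF`, `del_pHI_gt0`, `dup_pTS_gt0`
#'   appended.
#' @export
transform_scores <- function(profile) {
  sums <- intersect(.profile_cols, names(profile))
  if (any(vapply(profile[sums], function(x) any(x < 0), logical(1)))) {
    abort("Internal error: negative cumulative score encountered.",
          class = "cnvrisk_internal_error")
  }
  profile |>
    mutate(
      del_log_pLI = log1p(.data$del_sum_pLI),
      del_log_invLOEUF = log1p(.data$del_sum_invLOEUF),
      dup_log_pLI = log1p(.data$dup_sum_pLI),
      dup_log_invLOEUF = log1p(.data$dup_sum_invLOEUF),
      del_pHI_gt0 = as.numeric(.data$del_sum_pHI > 0),
      dup_pTS_gt0 = as.numeric(.data$dup_sum_pTS > 0)
    )
}

#' Exclude samples carrying known pathogenic CNVs
#'
#' A sample is excluded when any of its calls reciprocally overlaps a
#' listed pathogenic region of the same copy state at or above the
#' threshold: `overlap / length(call) >= reciprocal_overlap` and
#' `overlap / length(region) >= reciprocal_overlap` (0.5 by default, the
#' standard CNV-matching convention). All calls of an excluded sample are
#' removed so the downstream cohort can be subset consistently.
#'
#' @param calls CNV calls tibble.
#' @param pathogenic_regions Tibble with `chrom`, `start`, `end`, `type`
#'   (`"deletion"`/`"duplication"`); BED-style half-open coordinates.
#' @param reciprocal_overlap Threshold in (0, 1].
#' @return List with `calls` (retained) and `excluded_samples` (character).
#' @export
exclude_pathogenic <- function(calls, pathogenic_regions,
                               reciprocal_overlap = 0.5) {
  if (reciprocal_overlap <= 0 || reciprocal_overlap > 1) {
    abort("`reciprocal_overlap` must be in (0, 1].", class = "cnvrisk_config_error")
  }
  if (is.null(pathogenic_regions) || nrow(pathogenic_regions) == 0L) {
    warn("Empty pathogenic-region list; no samples excluded.")
    return(list(calls = calls, excluded_samples = character()))
  }
  excluded <- character()
  for (st in unique(calls$type)) {
    cc <- calls[calls$type == st, , drop = FALSE]
    rr <- pathogenic_regions[pathogenic_regions$type == st, , drop = FALSE]
    if (nrow(cc) == 0L || nrow(rr) == 0L) next
    c_gr <- GenomicRanges::GRanges(cc$chrom, IRanges::IRanges(cc$start + 1, cc$end))
    r_gr <- GenomicRanges::GRanges(rr$chrom, IRanges::IRanges(rr$start + 1, rr$end))
    hits <- GenomicRanges::findOverlaps(c_gr, r_gr)
    if (length(hits) == 0L) next
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ov <- pmin(cc$end[qi], rr$end[si]) - pmax(cc$start[qi], rr$start[si])
    len_c <- cc$end[qi] - cc$start[qi]
    len_r <- rr$end[si] - rr$start[si]
    match_hit <- ov / len_c >= reciprocal_overlap & ov / len_r >= reciprocal_overlap
    excluded <- c(excluded, cc$sample_id[qi][match_hit])
  }
  excluded <- sort(unique(excluded))
  list(
    calls = calls[!calls$sample_id %in% excluded, , drop = FALSE],
    excluded_samples = excluded
  )
}
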