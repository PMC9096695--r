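#' Simulate a gene annotation table
#'
#' Tiles `n_genes` non-overlapping genes over the simulated chromosomes and
#' draws the four gene-level scores used by the risk-score schemes: the
#' dosage-sensitivity probabilities pHI (haploinsufficiency) and pTS
#' (triplosensitivity), the loss-of-function intolerance probability pLI,
#' and LOEUF (loss-of-function observed/expected upper bound fraction).
#' The three probabilities are drawn from a right-skewed Beta(0.3, 2) so
#' most genes score near zero and a small tail is strongly dosage
#' sensitive, matching the skew that makes cumulative CNV risk scores
#' long-tailed; LOEUF is Gamma distributed with mass near 1.
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `start`,
#'   `end` (0-based, half-open), `pHI`, `pTS`, `pLI`, `LOEUF`.
#' @export
#' @examples
#' genes <- sim_gene_table(sim_config(n_genes = 50, seed = 1))
sim_gene_table <- function(config) {
  config <- validate_sim_config(config)
  set.seed(child_seed(config$seed, "genes"))
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  per_chrom <- diff(round(seq(0, config$n_genes, length.out = config$n_chromosomes + 1)))

  tiles <- purrr::map2(chroms, per_chrom, function(ch, k) {
    if (k == 0L) return(NULL)
    len <- pmax(round(rlnorm(k, log(3e4), 0.7)), 1000)
    # shrink if the draw cannot fit, then spread the slack as random gaps
    if (sum(len) > 0.9 * config$chromosome_length) {
      len <- pmax(round(len * 0.9 * config$chromosome_length / sum(len)), 1000)
    }
    gap_w <- runif(k + 1)
    gaps <- floor(gap_w / sum(gap_w) * (config$chromosome_length - sum(len)))
    start <- cumsum(gaps[seq_len(k)] + c(0, len[-k]))
    tibble(chrom = ch, start = start, end = start + len)
  })
  genes <- bind_rows(tiles)
  n <- nrow(genes)
  genes |>
    mutate(
      gene_id = sprintf("G%05d", row_number()),
      pHI = rbeta(n, 0.3, 2),
      pTS = rbeta(n, 0.3, 2),
      pLI = rbeta(n, 0.3, 2),
      LOEUF = pmax(rgamma(n, shape = 4, rate = 4), 0.03)
    ) |>
    select("gene_id", "chrom", "start", "end", "pHI", "pTS", "pLI", "LOEUF")
}

#' Simulate per-sample CNV calls
#'
#' Each individual carries a Poisson(`cnv_rate`) number of CNV calls.
#' Each call is a deletion with probability `deletion_fraction`, has a
#' lognormal length truncated below at `min_cnv_size` (so every call
#' survives the standard 50 kb size filter), and is placed uniformly at
#' random on a uniformly chosen chromosome, independently across samples.
#'
#' @param config A [sim_config()].
#' @param genes Gene table from [sim_gene_table()] (used only to validate
#'   that a genome exists; placement is independent of gene positions).
#' @return A tibble of calls: `sample_id`, `chrom`, `start`, `end`, `type`
#'   (`"deletion"`/`"duplication"`), `platform`, `qc_pass`. Samples with
#'   zero calls simply have no rows; downstream scoring re-inserts them
#'   with all-zero profiles.
#' @export
sim_cnv_calls <- function(config, genes) {
  config <- validate_sim_config(config)
  if (is.null(genes) || nrow(genes) == 0L) {
    abort("`genes` must be a non-empty gene table.", class = "cnvrisk_config_error")
  }
  set.seed(child_seed(config$seed, "cnv"))
  sample_ids <- sprintf("S%05d", seq_len(config$n_samples))
  n_calls <- rpois(config$n_samples, config$cnv_rate)
  total <- sum(n_calls)
  if (total == 0L) {
    return(tibble(
      sample_id = character(), chrom = character(), start = double(),
      end = double(), type = character(), platform = character(),
      qc_pass = logical()
    ))
  }
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  # length: lognormal truncated below at min_cnv_size via inverse CDF
  p_lo <- plnorm(config$min_cnv_size, config$size_log_mean, config$size_log_sd)
  u <- runif(total, p_lo, 1)
  len <- pmin(round(qlnorm(u, config$size_log_mean, config$size_log_sd)),
              config$chromosome_length / 10)
  chrom <- sample(chroms, total, replace = TRUE)
  start <- floor(runif(total, 0, config$chromosome_length - len))
  tibble(
    sample_id = rep(sample_ids, n_calls),
    chrom = chrom,
    start = start,
    end = start + len,
    type = if_else(runif(total) < config$deletion_fraction,
                   "deletion", "duplication"),
    platform = "illumina",
    qc_pass = TRUE
  )
}
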