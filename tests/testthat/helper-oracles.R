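# Independent brute-force oracles and tiny fixture builders. Everything here
# is deliberately naive (all-pairs loops, closed forms) so it cannot share a
# defect with the vectorized implementations it checks.

bf_genes_in_cnv <- function(cnv, genes, rule = "containment") {
  keep <- logical(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    if (genes$chrom[i] != cnv$chrom) next
    keep[i] <- if (rule == "containment") {
      genes$start[i] >= cnv$start && genes$end[i] <= cnv$end
    } else {
      genes$start[i] < cnv$end && genes$end[i] > cnv$start
    }
  }
  genes[keep, , drop = FALSE]
}

# All-pairs per-sample scoring with explicit interval-union merging.
bf_profile <- function(calls, genes, samples) {
  rows <- lapply(samples, function(s) {
    cc <- calls[calls$sample_id == s, , drop = FALSE]
    row <- list(sample_id = s)
    for (st in c("deletion", "duplication")) {
      cs <- cc[cc$type == st, , drop = FALSE]
      merged <- list()
      for (ch in unique(cs$chrom)) {
        x <- cs[cs$chrom == ch, , drop = FALSE]
        x <- x[order(x$start), , drop = FALSE]
        i <- 1
        while (i <= nrow(x)) {
          s0 <- x$start[i]; e0 <- x$end[i]; j <- i + 1
          while (j <= nrow(x) && x$start[j] <= e0) {
            e0 <- max(e0, x$end[j]); j <- j + 1
          }
          merged[[length(merged) + 1]] <- list(chrom = ch, start = s0, end = e0)
          i <- j
        }
      }
      ts <- 0; ng <- 0; spli <- 0; sinv <- 0; sdos <- 0
      for (m in merged) {
        ts <- ts + m$end - m$start
        g <- bf_genes_in_cnv(m, genes)
        ng <- ng + nrow(g)
        spli <- spli + sum(g$pLI)
        sinv <- sinv + sum(1 / g$LOEUF)
        sdos <- sdos + sum(if (st == "deletion") g$pHI else g$pTS)
      }
      p <- if (st == "deletion") "del_" else "dup_"
      row[[paste0(p, "total_size")]] <- ts
      row[[paste0(p, "n_genes")]] <- ng
      row[[paste0(p, "sum_pLI")]] <- spli
      row[[paste0(p, "sum_invLOEUF")]] <- sinv
      row[[if (st == "deletion") "del_sum_pHI" else "dup_sum_pTS"]] <- sdos
    }
    tibble::as_tibble(row)
  })
  dplyr::bind_rows(rows)
}

# Direct step-up definition: adj for the i-th sorted p is the minimum of
# m * p_(j) / j over all j at or above its rank.
bf_bh <- function(p, m = length(p)) {
  ord <- order(p)
  n <- length(p)
  adj_sorted <- numeric(n)
  for (i in seq_len(n)) {
    adj_sorted[i] <- min(1, min(m * p[ord][i:n] / (i:n)))
  }
  out <- numeric(n)
  out[ord] <- adj_sorted
  out
}

# Closed-form OLS via the normal equations, with t tests.
ols_oracle <- function(X, y) {
  XtX <- t(X) %*% X
  beta <- solve(XtX, t(X) %*% y)
  res <- y - X %*% beta
  dfres <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / dfres
  se <- sqrt(diag(s2 * solve(XtX)))
  tval <- drop(beta) / se
  list(beta = drop(beta), se = se, t = tval,
       p = 2 * pt(abs(tval), dfres, lower.tail = FALSE))
}

# Small deterministic fixtures -------------------------------------------

toy_genes <- function() {
  tibble::tibble(
    gene_id = paste0("G", 1:4),
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(100L, 500L, 2000L, 100L),
    end = c(300L, 900L, 2500L, 400L),
    pHI = c(0.8, 0.1, 0.5, 0.9),
    pTS = c(0.2, 0.6, 0.3, 0.1),
    pLI = c(0.9, 0.05, 0.7, 0.95),
    LOEUF = c(0.5, 1.2, 0.8, 0.25)
  )
}

toy_call <- function(sample_id = "S1", chrom = "chr1", start = 0,
                     end = 1000, type = "deletion") {
  tibble::tibble(sample_id = sample_id, chrom = chrom, start = start,
                 end = end, type = type, platform = "illumina",
                 qc_pass = TRUE)
}

random_fixture <- function(n_genes = 1000, n_cnvs = 200, seed = 42) {
  set.seed(seed)
  gs <- sort(sample.int(1e6, n_genes))
  genes <- tibble::tibble(
    gene_id = sprintf("G%04d", seq_len(n_genes)),
    chrom = sample(paste0("chr", 1:3), n_genes, replace = TRUE),
    start = gs,
    end = gs + sample(100:5000, n_genes, replace = TRUE),
    pHI = runif(n_genes), pTS = runif(n_genes), pLI = runif(n_genes),
    LOEUF = runif(n_genes, 0.1, 2)
  )
  cs <- sample.int(1e6, n_cnvs)
  calls <- tibble::tibble(
    sample_id = sprintf("S%03d", sample.int(50, n_cnvs, replace = TRUE)),
    chrom = sample(paste0("chr", 1:3), n_cnvs, replace = TRUE),
    start = cs,
    end = cs + sample(1000:100000, n_cnvs, replace = TRUE),
    type = sample(c("deletion", "duplication"), n_cnvs, replace = TRUE),
    platform = "illumina",
    qc_pass = TRUE
  )
  list(genes = genes, calls = calls)
}

small_config <- function(...) {
  sim_config(n_samples = 400, n_genes = 3000, n_imaged = 150, seed = 99, ...)
}
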