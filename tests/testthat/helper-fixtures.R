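# Fixture builders and independent brute-force oracles used across the suite.
# Oracles are written as explicit loops so they share no code path with the
# package implementation.

tiny_annotation <- function() {
  gene_annotation(data.frame(
    gene_id = c("a1", "a2", "b1", "x1", "x2", "xp", "y1", "ym1", "ym2", "ym3"),
    chromosome = c("1", "1", "2", "X", "X", "X", "Y", "Y", "Y", "Y"),
    length_bp = c(1000L, 2000L, 1500L, 1200L, 800L, 900L, 700L, 600L, 500L, 400L),
    is_par = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    is_y_marker = c(FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  ))
}

tiny_metadata <- function(n_blast = 4) {
  ids <- paste0("B", seq_len(n_blast))
  sample_metadata(data.frame(
    sample_id = paste(rep(ids, each = 2), c("ICM", "TE"), sep = "_"),
    blastocyst_id = rep(ids, each = 2),
    compartment = rep(c("ICM", "TE"), n_blast),
    stringsAsFactors = FALSE
  ))
}

random_counts <- function(genes, samples, seed = 1, lambda = 50) {
  set.seed(seed)
  x <- matrix(rpois(length(genes) * length(samples), lambda),
              nrow = length(genes), dimnames = list(genes, samples))
  expression_matrix(x, "counts")
}

# --- oracles ---------------------------------------------------------------

oracle_chisq <- function(tab) {
  n <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      e <- sum(tab[i, ]) * sum(tab[, j]) / n
      stat <- stat + (tab[i, j] - e)^2 / e
    }
  }
  stat
}

oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  running_min <- 1
  for (k in rev(seq_len(m))) {
    i <- ord[k]
    running_min <- min(running_min, p[i] * m / k)
    q[i] <- running_min
  }
  q
}

# per-sample per-chromosome reads-per-million over the expressed panel,
# X excluding PAR, as explicit loops
oracle_signal <- function(counts, annotation, expressed_genes) {
  samples <- colnames(counts)
  chroms <- unique(annotation$chromosome)
  out <- matrix(NA_real_, length(samples), length(chroms),
                dimnames = list(samples, chroms))
  for (s in samples) {
    depth <- 0
    for (g in expressed_genes) depth <- depth + counts[g, s]
    for (ch in chroms) {
      tot <- 0
      any_gene <- FALSE
      for (g in expressed_genes) {
        row <- which(annotation$gene_id == g)
        if (annotation$chromosome[row] == ch &&
            !(ch == "X" && annotation$is_par[row])) {
          tot <- tot + counts[g, s]
          any_gene <- TRUE
        }
      }
      out[s, ch] <- if (any_gene) 1e6 * tot / depth else NA
    }
  }
  out[, colSums(is.na(out)) == 0, drop = FALSE]
}

oracle_zscores <- function(signal, compartment_of) {
  z <- signal * NA_real_
  for (cp in unique(compartment_of)) {
    rows <- which(compartment_of == cp)
    for (k in seq_len(ncol(signal))) {
      vals <- signal[rows, k]
      mu <- sum(vals) / length(vals)
      ss <- 0
      for (v in vals) ss <- ss + (v - mu)^2
      sdv <- sqrt(ss / (length(vals) - 1))
      for (r in rows) {
        z[r, k] <- if (sdv == 0) 0 else (signal[r, k] - mu) / sdv
      }
    }
  }
  z
}
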