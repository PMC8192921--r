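# Independent literal-loop oracles. These deliberately avoid the package's
# vectorized code paths: every sum is written as an explicit loop over the
# defining formula, so agreement is evidence and not tautology.

BASES <- c("A", "C", "G", "T")

oracle_raw_moment <- function(m, a, b) {
  acc <- 0
  for (e in seq_len(nrow(m))) {
    for (f in seq_len(ncol(m))) {
      acc <- acc + e^a * f^b * m[e, f]
    }
  }
  acc
}

oracle_central_moment <- function(m, a, b) {
  u00 <- oracle_raw_moment(m, 0, 0)
  if (u00 == 0) return(if (a + b == 0) 0 else 0)
  xbar <- oracle_raw_moment(m, 1, 0) / u00
  ybar <- oracle_raw_moment(m, 0, 1) / u00
  acc <- 0
  for (e in seq_len(nrow(m))) {
    for (f in seq_len(ncol(m))) {
      acc <- acc + (e - xbar)^a * (f - ybar)^b * m[e, f]
    }
  }
  acc
}

oracle_hahn_moment <- function(m, tab, p, q) {
  if (p + 1 > nrow(tab) || q + 1 > nrow(tab)) return(0)  # order beyond basis
  acc <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      acc <- acc + m[i, j] * tab[p + 1, i] * tab[q + 1, j]
    }
  }
  acc
}

oracle_tally <- function(bases) {
  ch <- strsplit(bases, "")[[1]]
  out <- c(A = 0, C = 0, G = 0, T = 0)
  for (c in ch) out[c] <- out[c] + 1
  out
}

oracle_position_sum <- function(bases) {
  ch <- strsplit(bases, "")[[1]]
  out <- c(A = 0, C = 0, G = 0, T = 0)
  for (i in seq_along(ch)) out[ch[i]] <- out[ch[i]] + i
  out
}

oracle_prim <- function(bases, convention = "signed") {
  ch <- strsplit(bases, "")[[1]]
  m <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  for (p in BASES) {
    fp <- NA
    for (i in seq_along(ch)) if (ch[i] == p) { fp <- i; break }
    if (is.na(fp)) next
    for (q in BASES) {
      for (j in seq_along(ch)) {
        if (ch[j] == q) {
          d <- j - fp
          m[p, q] <- m[p, q] + if (convention == "signed") d else abs(d)
        }
      }
    }
  }
  m
}

# product-form Matthews correlation from the four counts
oracle_mcc_product <- function(pos_total, neg_total, fn, fp) {
  tp <- pos_total - fn
  tn <- neg_total - fp
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

# Mann-Whitney pair statistic: fraction of (positive, negative) pairs ranked
# correctly, ties counted one half
oracle_auc_pairs <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  acc <- 0
  for (sp in pos) {
    for (sn in neg) {
      acc <- acc + (sp > sn) + 0.5 * (sp == sn)
    }
  }
  acc / (length(pos) * length(neg))
}

random_bases <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

tiny_feature_matrix <- function(n_pos = 15, n_neg = 15, length = 60,
                                separation = 1, seed = 42) {
  build_feature_matrix(
    generate_synthetic_dataset(n_pos, n_neg, length, separation, seed))
}
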