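# Independent brute-force oracles. These deliberately re-derive every
# quantity with explicit loops over definitions, sharing no code with the
# package implementation.

oracle_chars <- function(seq) strsplit(seq, "")[[1]]

oracle_all_trinucs <- function(alphabet = c("A", "C", "G", "T")) {
  out <- character(0)
  for (a in alphabet) for (b in alphabet) for (d in alphabet) {
    out <- c(out, paste0(a, b, d))
  }
  out
}

# EIIP: mean per-base value times overlapping-count frequency, per Eq.-style
# definition, with an explicit counting loop.
oracle_eiip <- function(seq) {
  vals <- c(A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335)
  L <- nchar(seq)
  tri <- oracle_all_trinucs()
  out <- numeric(length(tri))
  for (t in seq_along(tri)) {
    count <- 0
    for (i in 1:(L - 2)) {
      if (substr(seq, i, i + 2) == tri[t]) count <- count + 1
    }
    ch <- oracle_chars(tri[t])
    out[t] <- mean(c(vals[ch[1]], vals[ch[2]], vals[ch[3]])) * count / (L - 2)
  }
  names(out) <- tri
  out
}

# PSTNP: positional frequency difference by explicit double loop.
oracle_pstnp_fit <- function(pos, neg, alphabet = c("A", "C", "G", "T")) {
  tri <- oracle_all_trinucs(alphabet)
  L <- nchar(pos[1])
  Z <- matrix(0, length(tri), L - 2, dimnames = list(tri, NULL))
  for (t in seq_along(tri)) {
    for (j in 1:(L - 2)) {
      fp <- 0
      for (s in pos) if (substr(s, j, j + 2) == tri[t]) fp <- fp + 1
      fn <- 0
      for (s in neg) if (substr(s, j, j + 2) == tri[t]) fn <- fn + 1
      Z[t, j] <- fp / length(pos) - fn / length(neg)
    }
  }
  Z
}

oracle_ds_reduce <- function(seq) {
  ch <- oracle_chars(seq)
  paste0(ifelse(ch %in% c("A", "T"), "A", "C"), collapse = "")
}

oracle_pstnp_encode <- function(seq, Z) {
  L <- nchar(seq)
  out <- numeric(L - 2)
  for (u in 1:(L - 2)) out[u] <- Z[substr(seq, u, u + 2), u]
  out
}

# Physicochemical Type-II features: explicit double-loop lagged products
# with the fixed 1/(L-k-1) normalizer, k = 2.
oracle_physchem <- function(seq, std_table, lam) {
  L <- nchar(seq)
  k <- 2
  props <- setdiff(names(std_table), "dinucleotide")
  H <- function(dinuc, p) {
    std_table[[p]][std_table$dinucleotide == dinuc]
  }
  out <- numeric(0)
  for (m in 1:lam) {
    for (p in props) {
      s <- 0
      for (i in 1:(L - k - m)) {
        di <- substr(seq, i, i + 1)
        dj <- substr(seq, i + m, i + m + 1)
        s <- s + H(di, p) * H(dj, p)
      }
      out <- c(out, s / (L - k - 1))
    }
  }
  out
}

# auROC by counting all positive-negative score pairs, ties worth 0.5.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Textbook confusion-matrix metrics from TP/TN/FP/FN.
oracle_metrics <- function(tp, tn, fp, fn) {
  mcc_den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  list(
    sn = tp / (tp + fn),
    sp = tn / (tn + fp),
    acc = (tp + tn) / (tp + tn + fp + fn),
    mcc = if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  )
}

# Shannon entropy (bits) of trinucleotides at one position.
oracle_entropy_at <- function(seqs, i) {
  tri <- substr(seqs, i, i + 2)
  p <- as.numeric(table(tri)) / length(tri)
  -sum(p * log2(p))
}

# MRMD score table by direct formula.
oracle_mrmd <- function(X, y, metric = "euclidean") {
  p <- ncol(X)
  std <- apply(X, 2, function(v) if (sd(v) == 0) rep(0, length(v)) else (v - mean(v)) / sd(v))
  rel <- numeric(p)
  for (i in 1:p) rel[i] <- if (sd(X[, i]) == 0) 0 else abs(cor(X[, i], y))
  D <- matrix(0, p, p)
  for (i in 1:p) for (j in 1:p) {
    if (i != j) D[i, j] <- sqrt(sum((std[, i] - std[, j])^2))
  }
  dist_term <- numeric(p)
  maxd <- max(D)
  for (i in 1:p) dist_term[i] <- mean(D[i, -i]) / maxd
  data.frame(feature = colnames(X), relevance = rel, distance = dist_term,
             score = rel + dist_term)
}

random_window <- function(L = 41L) {
  ch <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  ch[(L + 1) %/% 2] <- "A"
  paste0(ch, collapse = "")
}
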