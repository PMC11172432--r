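# Independent brute-force reference implementations, coded as literally as
# possible from the descriptor and metric definitions. They share no code
# with the package internals and exist only to cross-check them.

oracle_groups <- list(c("A", "G", "V"), c("I", "L", "F", "P"),
                      c("Y", "M", "T", "S"), c("H", "N", "Q", "W"),
                      c("R", "K"), c("D", "E"), c("C"))

oracle_group_of <- function(res) {
  for (g in seq_along(oracle_groups))
    if (res %in% oracle_groups[[g]]) return(g)
  NA_integer_
}

# C/T/D of one region, computed position by position
oracle_ctd <- function(region) {
  chars <- strsplit(region, "")[[1]]
  g <- vapply(chars, oracle_group_of, 0L)
  len <- length(g)
  comp <- vapply(1:7, function(k) sum(g == k) / len, 0)
  trans <- c()
  for (i in 1:6) for (j in (i + 1):7) {
    cnt <- 0
    if (len > 1) for (t in 1:(len - 1)) {
      if ((g[t] == i && g[t + 1] == j) || (g[t] == j && g[t + 1] == i))
        cnt <- cnt + 1
    }
    trans <- c(trans, if (len > 1) cnt / (len - 1) else 0)
  }
  dist <- c()
  for (k in 1:7) {
    pos <- which(g == k)
    if (length(pos) == 0) {
      dist <- c(dist, rep(0, 5))
    } else {
      n <- length(pos)
      picks <- c(pos[1], pos[ceiling(0.25 * n)], pos[ceiling(0.5 * n)],
                 pos[ceiling(0.75 * n)], pos[n])
      dist <- c(dist, picks / len)
    }
  }
  unname(c(comp, trans, dist))
}

oracle_regions <- function(L) {
  starts <- c(seq(0, 0.75, by = 0.125), 0, 0.125, 0.25)
  ends <- c(seq(0.25, 1, by = 0.125), 0.75, 0.875, 1)
  cbind(floor(starts * L) + 1, floor(ends * L))
}

oracle_ld <- function(sequence) {
  L <- nchar(sequence)
  reg <- oracle_regions(L)
  out <- c()
  for (r in 1:10)
    out <- c(out, oracle_ctd(substr(sequence, reg[r, 1], reg[r, 2])))
  out
}

# all 4/1/1/1 partitions of the 7 groups, G0 combinations in lexicographic
# order, leftover groups ascending into G1, G2, G3
oracle_partitions <- function() {
  out <- list()
  combos <- combn(7, 4)
  for (i in seq_len(ncol(combos))) {
    cls <- integer(7)
    cls[setdiff(1:7, combos[, i])] <- 1:3
    out[[i]] <- cls
  }
  out
}

# unit-circle placement and moment summary, one residue at a time
oracle_fvector <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  g <- vapply(chars, oracle_group_of, 0L)
  out <- c()
  for (cls in oracle_partitions()) {
    k <- cls[g]
    L <- length(k)
    tot <- vapply(0:3, function(kk) sum(k == kk), 0L)
    x <- y <- numeric(L)
    seen <- integer(4)
    for (j in 1:L) {
      seen[k[j] + 1] <- seen[k[j] + 1] + 1
      theta <- (seen[k[j] + 1] / (tot[k[j] + 1] + 1) + k[j]) * pi / 2
      x[j] <- cos(theta); y[j] <- sin(theta)
    }
    f1 <- mean(x); f3 <- mean(y)
    f2 <- if (L > 1) sum((x - f1)^2) / (L - 1) else 0
    f4 <- if (L > 1) sum((y - f3)^2) / (L - 1) else 0
    out <- c(out, f1, f2, f3, f4)
  }
  unname(out)
}

oracle_props <- local({
  tab <- read.delim(system.file("extdata", "apaac_properties.tsv",
                                package = "dfppi"))
  rownames(tab) <- tab$residue
  aas <- sort(tab$residue)
  std <- function(x) (x - mean(x)) / sqrt(sum((x - mean(x))^2) / length(x))
  list(aa = aas,
       h1 = setNames(std(tab[aas, "hydrophobicity"]), aas),
       h2 = setNames(std(tab[aas, "hydrophilicity"]), aas))
})

# pseudo-amino-acid composition variants, term by term
oracle_apaac <- function(sequence, lambda = 30, w1 = 0.5, w2 = 0.5,
                         plus = FALSE) {
  chars <- strsplit(sequence, "")[[1]]
  chars <- chars[chars %in% oracle_props$aa]
  L <- length(chars)
  h1 <- oracle_props$h1[chars]; h2 <- oracle_props$h2[chars]
  f <- vapply(oracle_props$aa, function(a) sum(chars == a) / L, 0)
  tau <- c()
  for (k in 1:lambda) {
    t1 <- t2 <- 0
    if (L - k >= 1) {
      for (i in 1:(L - k)) {
        t1 <- t1 + h1[i] * h1[i + k]
        t2 <- t2 + h2[i] * h2[i + k]
      }
      t1 <- t1 / (L - k); t2 <- t2 / (L - k)
    }
    tau <- c(tau, t1, t2)
  }
  if (!plus) {
    cn <- sum(f) + w1 * sum(tau)
    return(unname(c(f, w1 * tau) / cn))
  }
  ups <- c()
  for (k in 1:lambda) {
    u1 <- u2 <- 0
    if (L - 2 * k >= 1) {
      for (i in 1:(L - 2 * k)) {
        u1 <- u1 + h1[i] * h1[i + k] * h1[i + 2 * k]
        u2 <- u2 + h2[i] * h2[i + k] * h2[i + 2 * k]
      }
      u1 <- u1 / (L - 2 * k); u2 <- u2 / (L - 2 * k)
    }
    ups <- c(ups, u1, u2)
  }
  cn <- sum(f) + w1 * sum(tau) + w2 * sum(ups)
  unname(c(f, w1 * tau, w2 * ups) / cn)
}

# confusion-metric reference, straight from the defining ratios
oracle_metrics <- function(tp, tn, fp, fn) {
  p <- tp + fn; n <- tn + fp
  div <- function(a, b) if (b == 0) 0 else a / b
  c(acc = div(tp + tn, p + n),
    sen = div(tp, p),
    spe = div(tn, n),
    pre = div(tp, tp + fp),
    npv = div(tn, tn + fn),
    f1 = div(2 * tp, 2 * tp + fp + fn),
    mcc = div(tp * tn - fp * fn,
              sqrt(p) * sqrt(n) * sqrt(tp + fp) * sqrt(tn + fn)))
}

# AUROC as the exhaustive pairwise comparison statistic
oracle_auroc <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# AUPRC by walking distinct thresholds from high to low
oracle_auprc <- function(labels, scores) {
  ths <- sort(unique(scores), decreasing = TRUE)
  P <- sum(labels == 1)
  prev_rec <- 0; auc <- 0
  for (t in ths) {
    pred <- scores >= t
    tp <- sum(pred & labels == 1)
    prec <- tp / sum(pred)
    rec <- tp / P
    auc <- auc + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  auc
}

random_aa_sequence <- function(L) {
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M",
                 "N", "P", "Q", "R", "S", "T", "V", "W", "Y"),
               L, replace = TRUE), collapse = "")
}
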