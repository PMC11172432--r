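# Handcrafted sequence descriptors: local descriptor (composition /
# transition / distribution over ten overlapping regions), the unit-circle
# F-vector, and the amphiphilic pseudo-amino-acid composition with
# tripeptide extension. All descriptors are defined on the 20 standard
# residues; non-standard codes are stripped before encoding.

strip_nonstandard <- function(sequence) {
  gsub(sprintf("[^%s]", paste(AA_STANDARD, collapse = "")), "",
       toupper(sequence))
}

# residue string -> integer group vector (1..7)
seq_groups <- function(sequence, lut) {
  g <- lut[utf8ToInt(sequence)]
  if (anyNA(g)) stop("sequence contains residues outside the 20 standard codes")
  g
}

# unordered group-pair index, enumerated (1,2),(1,3),...,(1,7),(2,3),... = 1..21
pair_index_table <- local({
  m <- matrix(NA_integer_, 7, 7)
  k <- 0L
  for (i in 1:6) for (j in (i + 1):7) {
    k <- k + 1L
    m[i, j] <- k
    m[j, i] <- k
  }
  m
})

#' Split a sequence into the ten local-descriptor regions
#'
#' Region i of a length-L sequence spans 1-based positions
#' `floor(start * L) + 1` to `floor(end * L)` inclusive, where (start, end)
#' are the scheme's fractional boundaries.
#'
#' @param sequence Residue string (non-standard residues are stripped).
#' @param scheme A [region_scheme()].
#' @return Character vector of 10 region substrings.
#' @export
split_regions <- function(sequence, scheme = region_scheme()) {
  sequence <- strip_nonstandard(sequence)
  L <- nchar(sequence)
  if (L < 8L)
    stop("sequence must have at least 8 standard residues to form 10 regions")
  from <- floor(scheme[, "start"] * L) + 1
  to <- floor(scheme[, "end"] * L)
  substring(sequence, from, to)
}

# C/T/D on an integer group vector; returns 63 values:
# 7 composition + 21 transition + 35 distribution.
ctd_groups <- function(g) {
  len <- length(g)
  comp <- tabulate(g, 7L) / len
  trans <- numeric(21L)
  if (len > 1L) {
    a <- g[-len]; b <- g[-1L]
    diff <- a != b
    if (any(diff)) {
      idx <- pair_index_table[cbind(a[diff], b[diff])]
      trans <- tabulate(idx, 21L) / (len - 1L)
    }
  }
  dist <- numeric(35L)
  for (grp in 1:7) {
    pos <- which(g == grp)
    ng <- length(pos)
    if (ng > 0L) {
      picks <- pos[c(1L, ceiling(c(0.25, 0.5, 0.75) * ng), ng)]
      dist[(grp - 1L) * 5L + 1:5] <- picks / len
    }
  }
  c(comp, trans, dist)
}

#' Composition/transition/distribution encoding of one region
#'
#' Composition: the 7 group frequencies. Transition: for each of the 21
#' unordered group pairs, the fraction of adjacent residue positions whose
#' groups alternate between the pair. Distribution: for each group, the
#' sequence-length-normalized positions of its first, 25th-percentile,
#' median, 75th-percentile and last occurrence (zeros when absent).
#'
#' @param region Non-empty residue string over the standard alphabet.
#' @param groups A [group_alphabet()].
#' @return Numeric vector of length 63 (7 C + 21 T + 35 D).
#' @export
ctd_region_vector <- function(region, groups = group_alphabet()) {
  if (!nzchar(region)) stop("region must be non-empty")
  ctd_groups(seq_groups(region, group_lookup(groups)))
}

#' Local descriptor (630 dimensions)
#'
#' Concatenates, region by region, the 63-dimensional C/T/D vectors of the
#' ten overlapping regions: 10 x (7 + 21 + 35) = 630 values, ordered
#' region-major with C, then T, then D within each region.
#'
#' @inheritParams split_regions
#' @param groups A [group_alphabet()].
#' @return Numeric vector of length 630.
#' @export
ld_vector <- function(sequence, groups = group_alphabet(),
                      scheme = region_scheme()) {
  sequence <- strip_nonstandard(sequence)
  L <- nchar(sequence)
  if (L < 8L)
    stop("sequence must have at least 8 standard residues to form 10 regions")
  g <- seq_groups(sequence, group_lookup(groups))
  from <- floor(scheme[, "start"] * L) + 1
  to <- floor(scheme[, "end"] * L)
  out <- numeric(630L)
  for (r in 1:10)
    out[(r - 1L) * 63L + 1:63] <- ctd_groups(g[from[r]:to[r]])
  out
}

#' Enumerate the 35 four-class partitions of the seven groups
#'
#' Each partition places 4 of the 7 groups in class G0 and the remaining
#' three groups, in ascending group-index order, in classes G1, G2 and G3.
#' Partitions are enumerated in lexicographic order of the G0 combination,
#' giving choose(7, 4) = 35 assignments.
#'
#' @return A 35 x 7 integer matrix; entry (i, g) is the class (0..3) of
#'   group g under partition i.
#' @export
enumerate_partitions <- function() {
  combos <- utils::combn(7L, 4L)
  out <- matrix(0L, nrow = 35L, ncol = 7L)
  for (i in seq_len(ncol(combos))) {
    rest <- setdiff(1:7, combos[, i])
    out[i, rest] <- 1:3
  }
  out
}

# class vector (0..3) per residue -> unit-circle angles
circle_angles <- function(cls) {
  tot <- tabulate(cls + 1L, 4L)
  run <- integer(length(cls))
  for (k in 0:3) {
    idx <- which(cls == k)
    run[idx] <- seq_along(idx)
  }
  (run / (tot[cls + 1L] + 1) + cls) * (pi / 2)
}

#' Place a sequence's residues on the unit circle
#'
#' Residue j belonging to class Gk is mapped to angle
#' `(n_j(Gk) / (n(Gk) + 1) + k) * pi / 2`, where `n_j(Gk)` counts class-k
#' residues among the first j positions and `n(Gk)` is the class total, so
#' each class occupies one quadrant.
#'
#' @param sequence Residue string (non-standard residues stripped).
#' @param assignment Integer vector of length 7 giving the class (0..3) of
#'   each group, e.g. one row of [enumerate_partitions()].
#' @param groups A [group_alphabet()].
#' @return An L x 2 matrix of (x, y) unit-circle coordinates.
#' @export
circle_trace <- function(sequence, assignment, groups = group_alphabet()) {
  sequence <- strip_nonstandard(sequence)
  if (!nzchar(sequence)) stop("sequence must contain standard residues")
  g <- seq_groups(sequence, group_lookup(groups))
  theta <- circle_angles(assignment[g])
  cbind(x = cos(theta), y = sin(theta))
}

#' F-vector descriptor (140 dimensions)
#'
#' For each of the 35 four-class partitions of the seven physicochemical
#' groups, residues are placed on the unit circle (see [circle_trace()])
#' and the point cloud is summarized by the mean and the sample variance of
#' each coordinate: (f1, f2, f3, f4) = (mean x, var x, mean y, var y). The
#' 35 quadruples are concatenated in partition order. For a single-residue
#' sequence the variance terms are defined as 0.
#'
#' @inheritParams circle_trace
#' @return Numeric vector of length 140.
#' @export
fvector <- function(sequence, groups = group_alphabet()) {
  sequence <- strip_nonstandard(sequence)
  if (!nzchar(sequence)) stop("sequence must contain standard residues")
  g <- seq_groups(sequence, group_lookup(groups))
  L <- length(g)
  parts <- enumerate_partitions()
  out <- numeric(140L)
  for (i in 1:35) {
    theta <- circle_angles(parts[i, ][g])
    x <- cos(theta); y <- sin(theta)
    f1 <- mean(x); f3 <- mean(y)
    if (L > 1L) {
      f2 <- sum((x - f1)^2) / (L - 1L)
      f4 <- sum((y - f3)^2) / (L - 1L)
    } else f2 <- f4 <- 0
    out[(i - 1L) * 4L + 1:4] <- c(f1, f2, f3, f4)
  }
  out
}

#' Configuration for the pseudo-amino-acid composition descriptors
#'
#' @param lambda Maximum correlation lag (default 30).
#' @param w1 Weight of the dipeptide (pair) correlation terms (default 0.5).
#' @param w2 Weight of the tripeptide (triplet) correlation terms
#'   (default 0.5); only used by [apaacplus_vector()].
#' @return A list with class `apaac_config`.
#' @export
apaac_config <- function(lambda = 30L, w1 = 0.5, w2 = 0.5) {
  lambda <- as.integer(lambda)
  if (lambda < 1L) stop("lambda must be >= 1")
  if (w1 < 0 || w2 < 0) stop("weights must be non-negative")
  structure(list(lambda = lambda, w1 = w1, w2 = w2), class = "apaac_config")
}

# standard-residue index vector 1..20 (non-standard stripped); errors when
# fewer than `min_len` standard residues remain
aa_indices <- function(sequence, min_len) {
  sequence <- strip_nonstandard(sequence)
  if (nchar(sequence) < min_len)
    stop("sequence must contain at least ", min_len, " standard residues")
  idx <- match(strsplit(sequence, "")[[1]], AA_STANDARD)
  idx
}

# lag-correlation terms: for each lag k = 1..lambda the hydrophobicity then
# the hydrophilicity term (alternating), pairs for tau, triplets for ups.
lag_terms <- function(h1, h2, lambda, order = 2L) {
  L <- length(h1)
  out <- numeric(2L * lambda)
  for (k in seq_len(lambda)) {
    if (order == 2L) {
      if (L - k >= 1L) {
        i <- seq_len(L - k)
        out[2L * k - 1L] <- sum(h1[i] * h1[i + k]) / (L - k)
        out[2L * k] <- sum(h2[i] * h2[i + k]) / (L - k)
      }
    } else {
      if (L - 2L * k >= 1L) {
        i <- seq_len(L - 2L * k)
        out[2L * k - 1L] <- sum(h1[i] * h1[i + k] * h1[i + 2L * k]) / (L - 2L * k)
        out[2L * k] <- sum(h2[i] * h2[i + k] * h2[i + 2L * k]) / (L - 2L * k)
      }
    }
  }
  out
}

#' Amphiphilic pseudo-amino-acid composition (20 + 2*lambda dimensions)
#'
#' The classic descriptor: 20 normalized residue frequencies followed by
#' 2*lambda weighted sequence-order terms (hydrophobicity and hydrophilicity
#' correlations at lags 1..lambda, alternating), all divided by the
#' normalizer `C = sum(f) + w1 * sum(tau)`. Lags whose averaging window is
#' empty (lag >= sequence length) contribute 0.
#'
#' @param sequence Residue string; non-standard residues are stripped first.
#' @param cfg An [apaac_config()].
#' @param props A [property_table()].
#' @return Numeric vector of length `20 + 2 * lambda`.
#' @export
apaac_vector <- function(sequence, cfg = apaac_config(),
                         props = property_table()) {
  idx <- aa_indices(sequence, 1L)
  f <- tabulate(idx, 20L) / length(idx)
  tau <- lag_terms(props[idx, "h1"], props[idx, "h2"], cfg$lambda, order = 2L)
  cnorm <- sum(f) + cfg$w1 * sum(tau)
  c(f, cfg$w1 * tau) / cnorm
}

#' Amphiphilic pseudo-amino-acid composition with tripeptide terms
#' (20 + 4*lambda dimensions)
#'
#' Extends [apaac_vector()] with 2*lambda tripeptide correlation terms: for
#' lag k, the average over i of `h_i * h_(i+k) * h_(i+2k)` for the
#' hydrophobicity and hydrophilicity scales. The normalizer becomes
#' `C = sum(f) + w1 * sum(tau) + w2 * sum(upsilon)`. Terms whose averaging
#' window is empty (`L - k <= 0` or `L - 2k <= 0`) are set to 0, which keeps
#' short benchmark sequences encodable at the default lambda = 30.
#'
#' @inheritParams apaac_vector
#' @return Numeric vector of length `20 + 4 * lambda`.
#' @export
apaacplus_vector <- function(sequence, cfg = apaac_config(),
                             props = property_table()) {
  idx <- aa_indices(sequence, 2L)
  f <- tabulate(idx, 20L) / length(idx)
  h1 <- props[idx, "h1"]; h2 <- props[idx, "h2"]
  tau <- lag_terms(h1, h2, cfg$lambda, order = 2L)
  ups <- lag_terms(h1, h2, cfg$lambda, order = 3L)
  cnorm <- sum(f) + cfg$w1 * sum(tau) + cfg$w2 * sum(ups)
  c(f, cfg$w1 * tau, cfg$w2 * ups) / cnorm
}

#' Full handcrafted feature vector (910 dimensions at lambda = 30)
#'
#' Concatenation of the local descriptor (630), the F-vector (140) and the
#' tripeptide-extended pseudo-amino-acid composition (20 + 4*lambda = 140 at
#' the default lambda). This is the per-protein input of the model's
#' handcrafted channel.
#'
#' @inheritParams ld_vector
#' @param cfg An [apaac_config()].
#' @param props A [property_table()].
#' @return Numeric vector of length `630 + 140 + 20 + 4 * lambda`.
#' @export
handcrafted_vector <- function(sequence, groups = group_alphabet(),
                               scheme = region_scheme(),
                               cfg = apaac_config(),
                               props = property_table()) {
  c(ld_vector(sequence, groups, scheme),
    fvector(sequence, groups),
    apaacplus_vector(sequence, cfg, props))
}

#' Featurize a collection of protein records
#'
#' @param records Protein records data.frame (`id`, `sequence`).
#' @param descriptors Character vector among `"ld"`, `"fvector"`,
#'   `"apaac"`, `"apaacplus"`; features are concatenated in the given order.
#' @param groups,scheme,cfg,props Descriptor parameters.
#' @return Numeric matrix, one row per record (rownames = ids).
#' @export
featurize_records <- function(records,
                              descriptors = c("ld", "fvector", "apaacplus"),
                              groups = group_alphabet(),
                              scheme = region_scheme(),
                              cfg = apaac_config(),
                              props = property_table()) {
  records <- as_protein_records(records)
  descriptors <- match.arg(descriptors,
                           c("ld", "fvector", "apaac", "apaacplus"),
                           several.ok = TRUE)
  fns <- list(
    ld = function(s) ld_vector(s, groups, scheme),
    fvector = function(s) fvector(s, groups),
    apaac = function(s) apaac_vector(s, cfg, props),
    apaacplus = function(s) apaacplus_vector(s, cfg, props))
  encode <- function(s) unlist(lapply(descriptors, function(d) fns[[d]](s)),
                               use.names = FALSE)
  first <- encode(records$sequence[1])
  out <- matrix(0, nrow = nrow(records), ncol = length(first))
  out[1, ] <- first
  if (nrow(records) > 1L)
    for (i in 2:nrow(records)) out[i, ] <- encode(records$sequence[i])
  rownames(out) <- records$id
  out
}
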