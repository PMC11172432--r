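#' @keywords internal
#' @useDynLib dfppi, .registration = TRUE
"_PACKAGE"

# The 20 standard amino acids, alphabetical by one-letter code. This order
# fixes token ids 0..19 and the row order of every property table.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Non-standard / ambiguity codes carried as dedicated tokens 20..24.
AA_NONSTANDARD <- c("B", "O", "U", "X", "Z")

TOKEN_PAD <- 25L
TOKEN_VOCAB_SIZE <- 26L

#' Seven-group physicochemical amino-acid alphabet
#'
#' Groups the 20 standard residues into seven classes by dipole moment and
#' side-chain volume, the grouping conventionally used by local-descriptor
#' (composition/transition/distribution) encodings: \{A,G,V\}, \{I,L,F,P\},
#' \{Y,M,T,S\}, \{H,N,Q,W\}, \{R,K\}, \{D,E\}, \{C\}.
#'
#' @param groups Optional list of 7 character vectors overriding the default
#'   grouping. Must cover all 20 standard residues exactly once.
#' @return An object of class `group_alphabet`: a named integer vector
#'   mapping each standard residue to its group index in 1..7.
#' @examples
#' ga <- group_alphabet()
#' ga[["C"]]  # 7
#' @export
group_alphabet <- function(groups = NULL) {
  if (is.null(groups)) {
    groups <- list(c("A", "G", "V"),
                   c("I", "L", "F", "P"),
                   c("Y", "M", "T", "S"),
                   c("H", "N", "Q", "W"),
                   c("R", "K"),
                   c("D", "E"),
                   c("C"))
  }
  if (length(groups) != 7L)
    stop("a group alphabet must have exactly 7 groups")
  members <- unlist(groups)
  if (anyDuplicated(members) || !setequal(members, AA_STANDARD))
    stop("groups must partition the 20 standard residues")
  map <- integer(20L)
  names(map) <- AA_STANDARD
  for (g in seq_along(groups)) map[groups[[g]]] <- g
  structure(map, class = "group_alphabet")
}

# Fast residue -> group lookup table indexed by raw byte value (utf8 code).
group_lookup <- function(ga) {
  lut <- rep(NA_integer_, 128L)
  lut[utf8ToInt(paste(AA_STANDARD, collapse = "")) ] <- as.integer(ga)
  lut
}

#' Overlapping ten-region scheme for the local descriptor
#'
#' Ten sequence windows expressed as (start, end) fractions of the sequence
#' length: seven windows of 25% length starting at 0, 12.5, 25, 37.5, 50,
#' 62.5 and 75%, plus three windows of 75% length starting at 0, 12.5 and
#' 25%. The three long windows jointly cover the whole sequence.
#'
#' @param fractions Optional 10x2 numeric matrix of (start, end) fractions
#'   overriding the default layout.
#' @return An object of class `region_scheme`: a 10x2 matrix with columns
#'   `start` and `end`.
#' @export
region_scheme <- function(fractions = NULL) {
  if (is.null(fractions)) {
    starts25 <- seq(0, 0.75, by = 0.125)
    fractions <- rbind(cbind(starts25, starts25 + 0.25),
                       cbind(c(0, 0.125, 0.25), c(0.75, 0.875, 1)))
  }
  fractions <- as.matrix(fractions)
  if (nrow(fractions) != 10L || ncol(fractions) != 2L)
    stop("a region scheme is a 10 x 2 matrix of (start, end) fractions")
  if (any(fractions < 0) || any(fractions > 1) ||
      any(fractions[, 2] <= fractions[, 1]))
    stop("region fractions must satisfy 0 <= start < end <= 1")
  dimnames(fractions) <- list(NULL, c("start", "end"))
  structure(fractions, class = "region_scheme")
}

#' Standardized hydrophobicity and hydrophilicity table
#'
#' The per-residue hydrophobicity and hydrophilicity values used by the
#' amphiphilic pseudo-amino-acid composition, standardized over the 20
#' standard residues to zero mean and unit (population) standard deviation.
#' Raw values are shipped in `inst/extdata/apaac_properties.tsv`
#' (hydrophobicity after Tanford as tabulated for pseudo-amino-acid
#' composition; hydrophilicity after Hopp and Woods) and can be overridden.
#'
#' @param path Optional path to a TSV with columns `residue`, `hydrophobicity`,
#'   `hydrophilicity` covering the 20 standard residues.
#' @return An object of class `property_table`: a 20x2 matrix (rows named by
#'   residue in alphabetical order, columns `h1`, `h2`) of standardized values.
#' @export
property_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "apaac_properties.tsv", package = "dfppi")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("residue", "hydrophobicity", "hydrophilicity")
  if (!all(need %in% names(tab)))
    stop("property table needs columns: ", paste(need, collapse = ", "))
  if (!setequal(tab$residue, AA_STANDARD))
    stop("property table must cover the 20 standard residues")
  rownames(tab) <- tab$residue
  tab <- tab[AA_STANDARD, ]
  std <- function(x) (x - mean(x)) / sqrt(mean((x - mean(x))^2))
  out <- cbind(h1 = std(tab$hydrophobicity), h2 = std(tab$hydrophilicity))
  rownames(out) <- AA_STANDARD
  structure(out, class = "property_table")
}
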