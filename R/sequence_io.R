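#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file of amino-acid sequences (multi-line
#'   sequences allowed). The record id is the first whitespace-delimited
#'   token of the header.
#' @return A data.frame with columns `id` and `sequence` (uppercase).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  if (any(!nzchar(ids)))
    stop("FASTA record ", which(!nzchar(ids))[1], " has an empty header")
  if (anyDuplicated(ids))
    stop("duplicate FASTA id: ", ids[duplicated(ids)][1])
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("empty sequence for record: ", ids[empty][1])
  bad <- grepl("[^A-Z]", seqs)
  if (any(bad))
    stop("non-letter characters in sequence of record: ", ids[bad][1])
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write protein records to a FASTA file
#'
#' @param records data.frame with columns `id`, `sequence`.
#' @param path Output path.
#' @export
write_fasta <- function(records, path) {
  records <- as_protein_records(records)
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

# Validate a protein-record collection (id + non-empty sequence, unique ids).
as_protein_records <- function(records) {
  if (!is.data.frame(records) ||
      !all(c("id", "sequence") %in% names(records)))
    stop("protein records must be a data.frame with columns id, sequence")
  if (nrow(records) == 0L) stop("empty protein record collection")
  if (anyDuplicated(records$id))
    stop("duplicate record id: ", records$id[duplicated(records$id)][1])
  if (any(!nzchar(records$sequence))) stop("empty sequence in records")
  records
}

#' Read a protein-pair table
#'
#' Tab-separated table with columns id_a, id_b and an optional 0/1 label.
#' No header by default.
#'
#' @param path Path to the TSV file.
#' @param header Whether the file carries a header row.
#' @return A data.frame with columns `id_a`, `id_b` and, when present,
#'   integer `label` in \{0, 1\}.
#' @export
read_pair_table <- function(path, header = FALSE) {
  if (!file.exists(path)) stop("pair table not found: ", path)
  tab <- utils::read.delim(path, header = header, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L || ncol(tab) > 3L)
    stop("pair table must have 2 or 3 tab-separated columns, found ",
         ncol(tab))
  names(tab)[1:2] <- c("id_a", "id_b")
  if (ncol(tab) == 3L) {
    names(tab)[3] <- "label"
    lab <- suppressWarnings(as.integer(tab$label))
    if (anyNA(lab) || !all(lab %in% c(0L, 1L)))
      stop("pair labels must be 0 or 1")
    tab$label <- lab
  }
  tab
}

#' Write a protein-pair table
#'
#' @param pairs data.frame with columns `id_a`, `id_b` and optionally `label`.
#' @param path Output path.
#' @export
write_pair_table <- function(pairs, path) {
  cols <- intersect(c("id_a", "id_b", "label"), names(pairs))
  utils::write.table(pairs[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# token ids 0..19 for the standard residues (alphabetical), 20..24 for
# B, O, U, X, Z; unknown letters fold into the X token.
token_lut <- local({
  lut <- rep(NA_integer_, 128L)
  lut[vapply(AA_STANDARD, utf8ToInt, 0L)] <- 0:19
  lut[vapply(AA_NONSTANDARD, utf8ToInt, 0L)] <- 20:24
  x_token <- 20L + match("X", AA_NONSTANDARD) - 1L
  letters_idx <- utf8ToInt("A"):utf8ToInt("Z")
  lut[letters_idx][is.na(lut[letters_idx])] <- x_token
  lut
})

#' Tokenize a sequence and fix its length
#'
#' Maps residues to integer tokens: 0-19 for the 20 standard amino acids in
#' alphabetical order, 20-24 for the non-standard codes B, O, U, X, Z (any
#' other letter folds into the X token), and 25 as the padding token.
#' Sequences longer than `n` are truncated on the right; shorter ones are
#' right-padded with token 25.
#'
#' @param sequence Character scalar of residues (or a character vector, in
#'   which case a matrix with one row per sequence is returned).
#' @param n Fixed output length.
#' @return Integer vector of length `n` (or an `length(sequence)` x `n`
#'   integer matrix).
#' @examples
#' tokenize_and_pad("ACD", 5)  # 0 1 2 25 25
#' @export
tokenize_and_pad <- function(sequence, n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) stop("n must be a positive integer")
  one <- function(s) {
    toks <- token_lut[utf8ToInt(toupper(s))]
    if (anyNA(toks)) stop("sequence contains non-letter characters")
    if (length(toks) >= n) toks[seq_len(n)]
    else c(toks, rep(TOKEN_PAD, n - length(toks)))
  }
  if (length(sequence) == 1L) return(one(sequence))
  out <- matrix(TOKEN_PAD, nrow = length(sequence), ncol = n)
  for (i in seq_along(sequence)) out[i, ] <- one(sequence[i])
  out
}

#' Decode tokens back to residue letters
#'
#' Inverse of [tokenize_and_pad()] on the non-padding prefix.
#'
#' @param tokens Integer vector of tokens in 0..25.
#' @return Character scalar; padding tokens are dropped.
#' @export
detokenize <- function(tokens) {
  letters26 <- c(AA_STANDARD, AA_NONSTANDARD)
  tokens <- tokens[tokens != TOKEN_PAD]
  paste(letters26[tokens + 1L], collapse = "")
}

#' Mean sequence length (floored)
#'
#' The fixed token-sequence length is conventionally set to the average
#' sequence length of the training set; the floor of the arithmetic mean is
#' used as the integer rounding rule.
#'
#' @param records Protein records data.frame.
#' @return Positive integer.
#' @export
mean_sequence_length <- function(records) {
  records <- as_protein_records(records)
  as.integer(floor(mean(nchar(records$sequence))))
}
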