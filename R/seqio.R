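#' The 20-letter amino-acid alphabet, in the fixed encoding order
#'
#' Residue `aa_alphabet()[k]` is encoded as integer state `k`; the order is
#' alphabetical over the one-letter codes, so A -> 1, C -> 2, ..., Y -> 20.
#'
#' @return Character vector of the 20 standard one-letter residue codes.
#' @export
aa_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Read protein sequences from a FASTA file
#'
#' Reads a multi-record FASTA file into a tibble of protein records. The
#' header line is split into an `id` (first whitespace-delimited token) and a
#' free-text `label` (the remainder, `NA` if absent). Residues are uppercased
#' and sanitized against the standard 20-letter alphabet.
#'
#' @param path Path to a FASTA file.
#' @param alphabet_policy How to treat characters outside the 20-letter
#'   alphabet (gaps, stops, ambiguity codes such as X/B/Z/U/O): `"drop"`
#'   (default) removes them with one summary warning; `"error"` aborts on the
#'   first offending record.
#' @return A tibble with columns `id`, `label`, `residues` and `n_dropped`
#'   (characters removed per record). The total dropped count is attached as
#'   attribute `n_dropped`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">h1 human", "MKV"), fa)
#' read_protein_fasta(fa)
#' @export
read_protein_fasta <- function(path, alphabet_policy = c("drop", "error")) {
  alphabet_policy <- match.arg(alphabet_policy)
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) abort(paste0("no records in FASTA file: ", path))
  headers <- names(aa)
  id <- vapply(strsplit(headers, "\\s+"), `[`, character(1), 1L)
  if (any(is.na(id) | id == "")) abort("FASTA record with empty id")
  if (anyDuplicated(id)) {
    abort(paste0("duplicate record id(s): ",
                 paste(unique(id[duplicated(id)]), collapse = ", ")))
  }
  label <- trimws(sub("^\\S+\\s*", "", headers))
  label[label == ""] <- NA_character_
  raw <- toupper(as.character(aa))
  clean <- gsub(sprintf("[^%s]", paste(aa_alphabet(), collapse = "")), "", raw)
  n_dropped <- nchar(raw) - nchar(clean)
  if (alphabet_policy == "error" && any(n_dropped > 0L)) {
    bad <- id[n_dropped > 0L][1L]
    abort(paste0("record '", bad, "' contains non-standard residues"))
  }
  if (any(n_dropped > 0L)) {
    warn(sprintf("dropped %d non-standard character(s) across %d record(s)",
                 sum(n_dropped), sum(n_dropped > 0L)))
  }
  short <- nchar(clean) < 2L
  if (any(short)) {
    abort(paste0("record(s) shorter than 2 residues after sanitization: ",
                 paste(id[short], collapse = ", ")))
  }
  out <- tibble(id = unname(id), label = unname(label),
                residues = unname(clean), n_dropped = unname(n_dropped))
  attr(out, "n_dropped") <- sum(n_dropped)
  out
}

#' Encode a residue string as an integer state series
#'
#' Maps each residue through the fixed bijection A -> 1, C -> 2, ..., Y -> 20
#' (alphabetical order of the one-letter codes, see [aa_alphabet()]). Any
#' bijection gives identical mutual-information values -- MI depends only on
#' the state distribution, not the labels -- so this choice is frozen purely
#' for reproducibility.
#'
#' @param residues A single string over the 20-letter alphabet.
#' @return Integer vector of states in 1..20.
#' @examples
#' encode_sequence("ACD")  # 1 2 3
#' @export
encode_sequence <- function(residues) {
  stopifnot(is.character(residues), length(residues) == 1L)
  chars <- strsplit(residues, "", fixed = TRUE)[[1]]
  idx <- match(chars, aa_alphabet())
  if (anyNA(idx)) {
    abort(paste0("unknown residue(s): ",
                 paste(unique(chars[is.na(idx)]), collapse = ", ")))
  }
  idx
}

#' Decode an integer state series back to residues
#'
#' Inverse of [encode_sequence()].
#'
#' @param series Integer vector of states in 1..20.
#' @return A single residue string.
#' @export
decode_sequence <- function(series) {
  stopifnot(all(series >= 1L), all(series <= 20L))
  paste(aa_alphabet()[series], collapse = "")
}

#' Encode a tibble of protein records
#'
#' Adds a `series` list-column of integer state vectors to a tibble of
#' protein records (as returned by [read_protein_fasta()] or
#' [generate_families()]).
#'
#' @param proteins Tibble with columns `id` and `residues`.
#' @return The input tibble with a `series` list-column appended.
#' @export
encode_proteins <- function(proteins) {
  stopifnot(is.data.frame(proteins),
            all(c("id", "residues") %in% names(proteins)))
  dplyr::mutate(as_tibble(proteins),
                series = purrr::map(.data$residues, encode_sequence))
}
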