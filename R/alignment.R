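AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Construct an amino-acid alignment object
#'
#' @param seqs character vector of aligned sequences (equal lengths).
#' @param ids sequence identifiers (default: names of `seqs`).
#' @param species,gene,chromosome optional per-sequence annotation; when
#'   missing they are parsed from the identifiers with [parse_seq_ids()].
#' @return an object of class `aa_alignment`: a character matrix (rows =
#'   sequences, columns = sites, uppercase) with a `meta` attribute holding
#'   the per-sequence annotation data frame.
#' @export
aa_alignment <- function(seqs, ids = names(seqs), species = NULL,
                         gene = NULL, chromosome = NULL) {
  force(ids)
  seqs <- toupper(as.character(seqs))
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  if (anyDuplicated(ids)) stop("duplicated sequence identifiers")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: sequence lengths ", paste(unique(lens),
         collapse = ", "))
  if (lens[1] == 0L) stop("zero-length alignment")
  chars <- sort(unique(strsplit(paste(seqs, collapse = ""), "")[[1]]))
  if (!all(chars %in% c(LETTERS, "-", "*", ".")))
    stop("invalid alignment characters: ",
         paste(setdiff(chars, c(LETTERS, "-", "*", ".")), collapse = " "))
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- ids
  if (is.null(species) || is.null(gene)) {
    meta <- parse_seq_ids(ids)
  } else {
    meta <- data.frame(id = ids, species = species, gene = gene,
                       chromosome = if (is.null(chromosome))
                         NA_character_ else chromosome,
                       stringsAsFactors = FALSE)
  }
  attr(m, "meta") <- meta
  class(m) <- c("aa_alignment", class(m))
  m
}

#' Parse structured sequence identifiers
#'
#' The pipeline's identifier scheme is `species|gene|chromosome`, e.g.
#' `"Hsap|E2F1|20"` (a leading `chr` on the chromosome field is tolerated;
#' `-` marks an unknown chromosome).  Identifiers with fewer fields get `NA`
#' in the missing slots.
#'
#' @param ids character vector of identifiers.
#' @param sep field separator.
#' @return data frame with columns `id`, `species`, `gene`, `chromosome`.
#' @export
parse_seq_ids <- function(ids, sep = "|") {
  parts <- strsplit(ids, sep, fixed = TRUE)
  pick <- function(i) vapply(parts, function(p)
    if (length(p) >= i) p[i] else NA_character_, character(1))
  chrom <- sub("^chr", "", pick(3))
  chrom[chrom %in% c("-", "")] <- NA_character_
  data.frame(id = ids, species = pick(1), gene = pick(2),
             chromosome = chrom, stringsAsFactors = FALSE)
}

#' Read an aligned FASTA file of amino-acid sequences
#'
#' @param file path to an aligned FASTA file.
#' @param text optional character scalar with FASTA content in place of a
#'   file.
#' @param ref optional `species_ref`; when given, header species tokens are
#'   validated against the reference taxonomy.
#' @return an `aa_alignment` (see [aa_alignment()]).
#' @examples
#' a <- read_alignment(text = ">Hsap|g1|1\nACDE\n>Mmus|g1|-\nACDF\n")
#' ncol(a)
#' @export
read_alignment <- function(file = NULL, text = NULL, ref = NULL) {
  if (is.null(file)) {
    stopifnot(!is.null(text))
    file <- tempfile(fileext = ".fasta")
    on.exit(unlink(file))
    writeLines(text, file)
  }
  recs <- ape::read.FASTA(file, type = "AA")
  if (length(recs) == 0) stop("no sequences in FASTA input")
  seqs <- vapply(as.character(recs), paste, "", collapse = "")
  a <- aa_alignment(seqs, ids = names(recs))
  if (!is.null(ref)) {
    sp <- attr(a, "meta")$species
    bad <- setdiff(stats::na.omit(sp), ref$tree$tip.label)
    if (length(bad))
      stop("unknown species in sequence headers: ",
           paste(bad, collapse = ", "))
  }
  a
}

#' Write an alignment to FASTA
#'
#' @param a an `aa_alignment`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_alignment <- function(a, file) {
  stopifnot(inherits(a, "aa_alignment"))
  seqs <- apply(unclass(a), 1, paste, collapse = "")
  writeLines(paste0(">", rownames(a), "\n", seqs), file)
  invisible(file)
}

#' Remove all columns containing gaps or missing data
#'
#' Complete-deletion trimming: a column is kept only if every row carries one
#' of the 20 standard amino acids.  Gaps (`-`), ambiguity codes (`X`) and any
#' non-standard letter count as missing data and remove the column.  The
#' operation is idempotent.
#'
#' @param a an `aa_alignment`.
#' @return the trimmed `aa_alignment` (row order preserved).
#' @examples
#' a <- read_alignment(text = ">s1\nAC-E\n>s2\nACDE\n")
#' ncol(trim_complete_deletion(a))  # 3
#' @export
trim_complete_deletion <- function(a) {
  stopifnot(inherits(a, "aa_alignment"))
  m <- unclass(a)
  keep <- apply(matrix(m %in% AA20, nrow = nrow(m)), 2, all)
  if (!any(keep))
    stop("complete-deletion trimming removed every alignment column")
  out <- m[, keep, drop = FALSE]
  attr(out, "meta") <- attr(a, "meta")
  class(out) <- c("aa_alignment", class(out))
  out
}

#' @export
print.aa_alignment <- function(x, ...) {
  cat(sprintf("Amino-acid alignment: %d sequences x %d columns\n",
              nrow(x), ncol(x)))
  invisible(x)
}
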