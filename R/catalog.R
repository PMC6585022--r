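#' Parse a cytogenetic band into its chromosome token
#'
#' The chromosome is the maximal leading token of the band before the first
#' arm letter (`p`/`q`), e.g. `"20q13.33"` gives `"20"` and
#' `"1p36.13-p36.12"` gives `"1"`.  Bare chromosome tokens are accepted.
#'
#' @param band character vector of cytogenetic bands.
#' @return character vector of chromosome tokens (`"1"`..`"22"`, `"X"`,
#'   `"Y"`).
#' @examples
#' parse_cytoband(c("20q13.33", "Xq26.2", "1p36.13-p36.12"))
#' @export
parse_cytoband <- function(band) {
  band <- as.character(band)
  pos <- regexpr("^([0-9]{1,2}|X|Y)(?=$|[pq])", band, perl = TRUE)
  tok <- rep(NA_character_, length(band))
  tok[pos > 0] <- regmatches(band, pos)
  valid <- c(as.character(1:22), "X", "Y")
  bad <- is.na(tok) | !tok %in% valid
  if (any(bad))
    stop("malformed cytogenetic band: ", paste(band[bad], collapse = ", "))
  tok
}

#' Read a gene-family catalog table
#'
#' Reads one or more TSV catalog files (columns `family`, `gene`, `cytoband`,
#' optional `family_full`, `accession`, `source_study`) and derives the
#' chromosome token for each member.
#'
#' @param paths character vector of file paths.
#' @return a data frame of class `gene_catalog` with one row per family
#'   member and columns `family`, `family_full`, `gene`, `cytoband`,
#'   `chromosome`, `accession`, `source_study`.
#' @export
read_family_catalog <- function(paths) {
  parts <- lapply(paths, utils::read.delim, comment.char = "#",
                  stringsAsFactors = FALSE, na.strings = "NA")
  cat <- do.call(rbind, parts)
  need <- c("family", "gene", "cytoband")
  if (!all(need %in% names(cat)))
    stop("catalog must have columns: ", paste(need, collapse = ", "))
  for (opt in c("family_full", "accession", "source_study"))
    if (!opt %in% names(cat)) cat[[opt]] <- NA_character_
  cat$source_study[is.na(cat$source_study)] <- "present"
  cat$chromosome <- parse_cytoband(cat$cytoband)
  dup <- stats::aggregate(gene ~ family, cat, function(g) anyDuplicated(g) > 0)
  if (any(dup$gene))
    stop("duplicated gene symbols within family: ",
         paste(dup$family[dup$gene], collapse = ", "))
  sizes <- table(cat$family)
  if (any(sizes < 2))
    stop("families with fewer than 2 members: ",
         paste(names(sizes)[sizes < 2], collapse = ", "))
  cat <- cat[, c("family", "family_full", "gene", "cytoband", "chromosome",
                 "accession", "source_study")]
  class(cat) <- c("gene_catalog", "data.frame")
  cat
}

#' The packaged Hsa 1/2/8/20 gene-family catalog
#'
#' Loads the packaged catalog of human gene families with three- or four-fold
#' representation on chromosomes 1, 2, 8 and 20: the 25 families of the
#' present survey (125 members, with accessions), optionally together with
#' the named families of the earlier survey that re-enter the congruence
#' analysis (member rows reconstructed from public annotation; see the
#' fixture header).
#'
#' @param source `"present"`, `"previous"` or `"both"`.
#' @return a `gene_catalog` data frame (see [read_family_catalog()]).
#' @examples
#' cat25 <- paralogon_catalog()
#' length(unique(cat25$family))
#' @export
paralogon_catalog <- function(source = c("present", "previous", "both")) {
  source <- match.arg(source)
  paths <- switch(source,
    present  = pkg_extdata("table1_families.tsv"),
    previous = pkg_extdata("previous_families_synthetic.tsv"),
    both     = c(pkg_extdata("table1_families.tsv"),
                 pkg_extdata("previous_families_synthetic.tsv")))
  read_family_catalog(paths)
}

#' Fold of representation of gene families on a target chromosome set
#'
#' The fold of a family is the number of distinct target chromosomes carrying
#' at least one member.  With the canonical four-chromosome target a family
#' is `quadruplicated` at fold 4, `triplicated` at fold 3, and
#' `below-threshold` otherwise.  Members on non-target chromosomes stay in
#' the family (they are treated as translocated copies downstream) but do not
#' contribute to the fold.
#'
#' @param catalog a `gene_catalog` data frame (or any data frame with
#'   `family` and `chromosome` columns).
#' @param target character vector of target chromosome tokens.
#' @return data frame with columns `family`, `fold`, `label`.
#' @examples
#' fold_classification(paralogon_catalog(), c("1", "2", "8", "20"))
#' @export
fold_classification <- function(catalog, target = c("1", "2", "8", "20")) {
  if (length(target) == 0) stop("target chromosome set must be nonempty")
  target <- as.character(target)
  fams <- sort(unique(catalog$family))
  fold <- vapply(fams, function(f)
    length(intersect(unique(catalog$chromosome[catalog$family == f]), target)),
    integer(1))
  label <- ifelse(fold == 4, "quadruplicated",
                  ifelse(fold == 3, "triplicated", "below-threshold"))
  data.frame(family = fams, fold = unname(fold), label = unname(label),
             stringsAsFactors = FALSE)
}

#' Summarise a gene-family catalog
#'
#' Counts families by fold label and by source study, and counts members both
#' overall and restricted to the target chromosomes.
#'
#' @inheritParams fold_classification
#' @return list with elements `n_families`, `by_label` (named counts),
#'   `by_source` (named counts), `n_members`, `n_members_on_target` and the
#'   per-family `folds` table.
#' @examples
#' catalog_summary(paralogon_catalog())
#' @export
catalog_summary <- function(catalog, target = c("1", "2", "8", "20")) {
  folds <- fold_classification(catalog, target)
  labels <- c("quadruplicated", "triplicated", "below-threshold")
  by_label <- stats::setNames(
    vapply(labels, function(l) sum(folds$label == l), integer(1)), labels)
  src <- if ("source_study" %in% names(catalog)) {
    fam_src <- unique(catalog[, c("family", "source_study")])
    table(fam_src$source_study)
  } else table(character(0))
  out <- list(n_families = nrow(folds),
              by_label = by_label,
              by_source = c(src),
              n_members = nrow(catalog),
              n_members_on_target =
                sum(catalog$chromosome %in% as.character(target)),
              folds = folds)
  class(out) <- "catalog_summary"
  out
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat("Gene-family catalog summary\n")
  cat("  families:", x$n_families, "\n")
  for (l in names(x$by_label))
    cat(sprintf("    %-16s %d\n", l, x$by_label[[l]]))
  if (length(x$by_source)) {
    cat("  by source study:",
        paste(sprintf("%s=%d", names(x$by_source), x$by_source),
              collapse = ", "), "\n")
  }
  cat("  members:", x$n_members,
      sprintf("(%d on target chromosomes)\n", x$n_members_on_target))
  invisible(x)
}
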