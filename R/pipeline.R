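#' Assemble a pipeline configuration
#'
#' All stages of [run_pipeline()] read their parameters from this single
#' object, and the configuration is serialised (as JSON) into every output
#' directory so a run can be reproduced exactly.
#'
#' @param seed integer seed driving all randomness (bootstrap resampling and,
#'   when a scenario is attached, the simulator).
#' @param target target chromosome set for fold classification.
#' @param dist distance model, `"p"` or `"poisson"`.
#' @param B bootstrap pseudo-replicates.
#' @param min_support bootstrap threshold (percent) for duplication events
#'   entering the congruence stage; `NA` disables filtering.
#' @param window focal epoch bin for schematic topologies.
#' @param k translocation allowance for grouping (scalar or per-pair table,
#'   see [co_duplication_groups()]).
#' @param drop_discordant drop leaves flagged by
#'   [flag_discordant_leaves()] before duplication inference.
#' @param scenario optional [scenario_spec()]; when present the pipeline
#'   simulates its input and reports a truth comparison.
#' @param catalog optional `gene_catalog` for the catalog summary section.
#' @param outdir optional output directory for the report bundle.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed, target = c("1", "2", "8", "20"),
                            dist = c("p", "poisson"), B = 1000,
                            min_support = 50, window = "B2", k = 3,
                            drop_discordant = FALSE, scenario = NULL,
                            catalog = NULL, outdir = NULL) {
  if (missing(seed)) stop("a pipeline seed is mandatory")
  dist <- match.arg(dist)
  structure(list(seed = as.integer(seed), target = as.character(target),
                 dist = dist, B = B, min_support = min_support,
                 window = window, k = k,
                 drop_discordant = isTRUE(drop_discordant),
                 scenario = scenario, catalog = catalog, outdir = outdir),
            class = "pipeline_config")
}

#' Run the full duplication-dating and congruence pipeline
#'
#' Orchestrates, per family: complete-deletion trimming, NJ tree inference
#' with bootstrap support, outgroup rooting with invertebrate sequences
#' (falling back to the most divergent leaf when no invertebrate is
#' present), optional discordant-leaf screening, species-overlap duplication
#' detection and epoch dating; then across families: support filtering, the
#' epoch histogram, schematic-topology extraction for the focal window (with
#' exclusions logged) and co-duplication grouping.  With a `scenario` in the
#' configuration, input alignments are simulated and the report includes the
#' true event bins and co-duplication partition for comparison.
#'
#' @param config a [pipeline_config()].
#' @param alignments named list of `aa_alignment` objects (one per family);
#'   omitted when `config$scenario` is given.
#' @param ref a `species_ref` (default: the packaged reference).
#' @return a `paralogon_report` list with elements `trees`, `events`
#'   (dated, unfiltered), `events_kept` (after support filtering),
#'   `histogram`, `schematics`, `exclusions`, `groups`, `discordant`,
#'   `catalog_summary`, `truth` and `config`.  When `config$outdir` is set
#'   the bundle is also written as newick/TSV/JSON files.
#' @export
run_pipeline <- function(config, alignments = NULL,
                         ref = load_reference_taxonomy()) {
  stopifnot(inherits(config, "pipeline_config"))
  truth <- NULL
  if (!is.null(config$scenario)) {
    truth <- simulate_family_trees(config$scenario, ref)
    alignments <- evolve_sequences(truth)
  }
  report <- list(config = config, truth = truth)
  if (!is.null(config$catalog)) {
    report$catalog_summary <- catalog_summary(config$catalog, config$target)
  }
  if (!is.null(alignments)) {
    if (is.null(names(alignments)) || anyDuplicated(names(alignments)))
      stop("alignments must be a uniquely named list")
    fams <- names(alignments)
    trees <- list(); discordant <- list()
    all_events <- list(); schematics <- list(); exclusions <- character(0)
    for (fi in seq_along(fams)) {
      fam <- fams[fi]
      a <- trim_complete_deletion(alignments[[fam]])
      tr <- bootstrap_support(a, B = config$B, seed = config$seed + fi,
                              dist = config$dist)
      rt <- root_tree(tr, pipeline_outgroup(tr, ref))
      flagged <- flag_discordant_leaves(rt, ref)
      discordant[[fam]] <- flagged
      if (config$drop_discordant && length(flagged) &&
          ape::Ntip(rt) - length(flagged) >= 3) {
        rt <- ape::drop.tip(rt, flagged)
      }
      trees[[fam]] <- rt
      ev <- detect_duplications(rt, ref)
      ev <- date_duplications(ev, rt, ref, family = fam)
      all_events[[fam]] <- ev
    }
    events <- do.call(rbind, all_events)
    kept <- if (is.na(config$min_support)) {
      ev2 <- events; ev2$support_flag <- ""; ev2
    } else {
      suppressWarnings(filter_by_support(events, config$min_support))
    }
    for (fam in fams) {
      s <- tryCatch(
        schematic_topology(trees[[fam]],
                           kept[kept$family == fam, , drop = FALSE],
                           ref, window = config$window, family = fam),
        paralogon_exclusion = function(e) e)
      if (inherits(s, "paralogon_exclusion")) {
        exclusions <- c(exclusions, stats::setNames(conditionMessage(s), fam))
      } else {
        schematics[[fam]] <- s
      }
    }
    report$trees <- trees
    report$discordant <- discordant
    report$events <- events
    report$events_kept <- kept
    report$histogram <- epoch_histogram(kept)
    report$schematics <- schematics
    report$exclusions <- exclusions
    report$groups <- if (length(schematics))
      co_duplication_groups(schematics, k = config$k) else NULL
  }
  class(report) <- "paralogon_report"
  if (!is.null(config$outdir)) write_report(report, config$outdir)
  report
}

# invertebrate sequences root each tree; if none survive, fall back to the
# leaf most distant from all others (a midpoint-style last resort)
pipeline_outgroup <- function(tree, ref) {
  sp <- parse_seq_ids(tree$tip.label)$species
  out <- tree$tip.label[sp %in% ref$clades$invertebrate]
  if (length(out) && length(out) < ape::Ntip(tree)) return(out)
  dm <- ape::cophenetic.phylo(tree)
  tree$tip.label[which.max(rowSums(dm))]
}

#' Fraction of true duplication nodes recovered in their true epoch bin
#'
#' For a report produced from a simulated scenario, compares the per-family,
#' per-bin counts of inferred duplication events (before support filtering)
#' against the ground truth's observable duplication nodes.  A true node
#' counts as recovered if the pipeline dates an event of the same family to
#' the same bin (counts are matched, so surplus inferred events in a bin do
#' not help).
#'
#' @param report a `paralogon_report` from a run with a scenario.
#' @return fraction in `[0, 1]`.
#' @export
epoch_recovery <- function(report) {
  stopifnot(inherits(report, "paralogon_report"))
  if (is.null(report$truth)) stop("report carries no simulation ground truth")
  tot <- 0L; hit <- 0L
  for (fam in names(report$truth$families)) {
    tb <- table(report$truth$families[[fam]]$true_bins)
    ib <- table(report$events$bin[report$events$family == fam])
    for (b in names(tb)) {
      tot <- tot + tb[[b]]
      hit <- hit + min(tb[[b]], if (b %in% names(ib)) ib[[b]] else 0L)
    }
  }
  if (tot == 0L) return(NA_real_)
  hit / tot
}

#' True and inferred co-duplication partitions of simulated families
#'
#' Families excluded from the congruence stage (fewer than two window
#' duplications) form their own singleton groups in the inferred partition,
#' mirroring how families without a co-duplication signal are treated in a
#' real survey.
#'
#' @param report a `paralogon_report` from a run with a scenario.
#' @return data frame with columns `family`, `true_group`,
#'   `inferred_group`.
#' @export
co_duplication_partitions <- function(report) {
  stopifnot(inherits(report, "paralogon_report"))
  if (is.null(report$truth)) stop("report carries no simulation ground truth")
  fams <- names(report$truth$families)
  inferred <- integer(length(fams))
  names(inferred) <- fams
  ngrp <- 0L
  if (!is.null(report$groups)) {
    inferred[names(report$groups$membership)] <- report$groups$membership
    ngrp <- max(report$groups$membership)
  }
  for (f in fams) if (inferred[f] == 0L) {
    ngrp <- ngrp + 1L
    inferred[f] <- ngrp
  }
  data.frame(family = fams,
             true_group = unname(report$truth$partition[fams]),
             inferred_group = unname(inferred))
}

#' @export
print.paralogon_report <- function(x, ...) {
  cat("paralogon pipeline report\n")
  if (!is.null(x$catalog_summary)) print(x$catalog_summary)
  if (!is.null(x$events)) {
    cat("  families analysed:", length(x$trees), "\n")
    cat("  duplication events (dated/kept):", nrow(x$events), "/",
        nrow(x$events_kept), "\n")
    cat("  epoch totals:",
        paste(sprintf("%s=%d", colnames(x$histogram),
                      x$histogram["total", ]), collapse = " "), "\n")
    if (!is.null(x$groups))
      cat("  co-duplicated groups:", length(x$groups$groups), "\n")
    if (length(x$exclusions))
      cat("  families excluded from congruence:",
          paste(names(x$exclusions), collapse = ", "), "\n")
  }
  invisible(x)
}

write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg <- report$config
  cfg_json <- cfg[c("seed", "target", "dist", "B", "min_support", "window",
                    "drop_discordant")]
  cfg_json$k <- if (is.data.frame(cfg$k)) "per-pair table" else cfg$k
  cfg_json$scenario <- if (!is.null(cfg$scenario))
    unclass(cfg$scenario)[setdiff(names(cfg$scenario), "placements")]
  jsonlite::write_json(cfg_json, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (!is.null(report$trees)) {
    tdir <- file.path(outdir, "trees")
    dir.create(tdir, showWarnings = FALSE)
    for (fam in names(report$trees))
      ape::write.tree(report$trees[[fam]],
                      file.path(tdir, paste0(fam, ".nwk")))
    ev <- flatten_events(report$events)
    utils::write.table(ev, file.path(outdir, "events.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(report$histogram),
                       file.path(outdir, "histogram.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    sch <- data.frame(
      family = names(report$schematics),
      schematic = vapply(report$schematics, format, ""),
      symmetry = vapply(report$schematics, schematic_symmetry, ""),
      stringsAsFactors = FALSE)
    utils::write.table(sch, file.path(outdir, "schematics.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(report$groups)) {
      g <- report$groups
      gdf <- data.frame(
        group = seq_along(g$groups),
        families = vapply(g$groups, paste, "", collapse = ","),
        consensus = g$consensus, symmetry = g$symmetry,
        stringsAsFactors = FALSE)
      utils::write.table(gdf, file.path(outdir, "groups.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    if (length(report$exclusions))
      writeLines(paste(names(report$exclusions), report$exclusions,
                       sep = "\t"),
                 file.path(outdir, "exclusions.tsv"))
  }
  if (!is.null(report$truth)) {
    tt <- do.call(rbind, lapply(report$truth$families,
                                function(f) f$events))
    utils::write.table(tt, file.path(outdir, "truth_events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    part <- data.frame(family = names(report$truth$partition),
                       true_group = unname(report$truth$partition))
    if (!is.null(report$groups))
      part$inferred_group <-
        unname(report$groups$membership[part$family])
    utils::write.table(part, file.path(outdir, "truth_partition.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$catalog_summary)) {
    cs <- report$catalog_summary
    utils::write.table(cs$folds, file.path(outdir, "catalog_folds.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(n_families = cs$n_families, by_label = as.list(cs$by_label),
           by_source = as.list(cs$by_source), n_members = cs$n_members,
           n_members_on_target = cs$n_members_on_target),
      file.path(outdir, "catalog_summary.json"), auto_unbox = TRUE,
      digits = NA)
  }
  invisible(outdir)
}

flatten_events <- function(events) {
  ev <- events
  ev$left_species <- vapply(ev$left_species, paste, "", collapse = ",")
  ev$right_species <- vapply(ev$right_species, paste, "", collapse = ",")
  ev
}
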