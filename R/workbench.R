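# Tabular I/O for interactions, features and benchmark directories.
# All tables are TSV with header rows.

#' Build a DTIDataset from in-memory pieces
#'
#' @param interactions data.frame with columns `drug`, `target` and either
#'   `label` (+1/-1) or `value` (raw affinity, binarized here).
#' @param drugFeatures,targetFeatures numeric matrices with entity row
#'   names.
#' @param threshold,direction binarization rule applied when only `value`
#'   is present: `direction = "ge"` (default) labels `value >= threshold`
#'   positive (higher affinity score = stronger binding); `"le"` inverts
#'   the rule for raw dissociation-constant scales where lower is stronger.
#' @return a [DTIDataset-class].
#' @export
dtiDataset <- function(interactions, drugFeatures, targetFeatures,
                       threshold = 3, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  interactions <- as.data.frame(interactions)
  if (!all(c("drug", "target") %in% names(interactions))) {
    stop("interactions need 'drug' and 'target' columns")
  }
  if (!"label" %in% names(interactions)) {
    if (!"value" %in% names(interactions)) {
      stop("interactions need a 'label' or 'value' column")
    }
    v <- as.numeric(interactions$value)
    pos <- if (direction == "ge") v >= threshold else v <= threshold
    interactions$label <- ifelse(pos, 1, -1)
  }
  interactions$drug <- as.character(interactions$drug)
  interactions$target <- as.character(interactions$target)
  new("DTIDataset",
    interactions = interactions,
    drugFeatures = drugFeatures, targetFeatures = targetFeatures
  )
}

#' Read an interaction table
#'
#' Expects a TSV with header columns `drug`, `target` and `label` or
#' `value`. Raw affinity values are binarized at `threshold` with the
#' configurable `direction`; pre-binarized labels (+1/-1 or 0/1) pass
#' through. Duplicate (drug, target) rows are rejected.
#'
#' @param file path to a TSV file.
#' @inheritParams dtiDataset
#' @return a data.frame with columns `drug`, `target`, `label` (and
#'   `value` when present).
#' @export
loadInteractions <- function(file, threshold = 3, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (!all(c("drug", "target") %in% names(tab))) {
    stop("interaction file needs 'drug' and 'target' columns")
  }
  if (anyDuplicated(paste(tab$drug, tab$target, sep = "\r"))) {
    stop("duplicate (drug, target) rows in interaction file")
  }
  if ("label" %in% names(tab)) {
    lab <- as.numeric(tab$label)
    if (all(lab %in% c(0, 1))) lab <- ifelse(lab == 1, 1, -1)
    if (!all(lab %in% c(-1, 1))) stop("labels must be +1/-1 (or 0/1)")
    tab$label <- lab
  } else if ("value" %in% names(tab)) {
    v <- as.numeric(tab$value)
    if (any(is.na(v))) stop("non-numeric affinity values")
    pos <- if (direction == "ge") v >= threshold else v <= threshold
    tab$label <- ifelse(pos, 1, -1)
  } else {
    stop("interaction file needs a 'label' or 'value' column")
  }
  tab
}

#' Read a feature table
#'
#' TSV with a header; first column `id`, remaining columns numeric feature
#' values of fixed width. Duplicate or missing ids and non-numeric cells
#' are errors.
#'
#' @param file path to a TSV file.
#' @return a numeric matrix with ids as row names.
#' @export
loadFeatures <- function(file) {
  tab <- utils::read.delim(file, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("feature file needs an id column plus features")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) stop("duplicate entity ids in feature file")
  X <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(X) || any(is.na(X))) stop("non-numeric feature values")
  rownames(X) <- ids
  X
}

#' Write a feature matrix as TSV
#'
#' @param X numeric matrix with entity row names.
#' @param file output path.
#' @export
writeFeatures <- function(X, file) {
  df <- data.frame(id = rownames(X), X, check.names = FALSE)
  colnames(df) <- c("id", paste0("f", seq_len(ncol(X))))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write an interaction table as TSV
#'
#' @param interactions data.frame with `drug`, `target`, `label`.
#' @param file output path.
#' @export
writeInteractions <- function(interactions, file) {
  utils::write.table(interactions, file,
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(file)
}

#' Write a complete benchmark directory
#'
#' Emits the TSV dialects read back by [loadBenchmark()]:
#' `interactions.tsv`, `drug_features.tsv`, `target_features.tsv`,
#' `drug_hierarchy.tsv`, `target_hierarchy.tsv` and a small `meta.json`
#' recording the hierarchy kinds.
#'
#' @param bench a benchmark list as returned by [synthBenchmark()].
#' @param dir output directory (created if missing).
#' @export
writeBenchmark <- function(bench, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeInteractions(bench$data@interactions, file.path(dir, "interactions.tsv"))
  writeFeatures(bench$data@drugFeatures, file.path(dir, "drug_features.tsv"))
  writeFeatures(bench$data@targetFeatures, file.path(dir, "target_features.tsv"))
  writeHierarchy(bench$drugTree, file.path(dir, "drug_hierarchy.tsv"))
  writeHierarchy(bench$targetTree, file.path(dir, "target_hierarchy.tsv"))
  jsonlite::write_json(
    list(
      drugKind = bench$drugTree@kind, targetKind = bench$targetTree@kind,
      drugSpecialGroups = bench$drugTree@specialGroups,
      targetSpecialGroups = bench$targetTree@specialGroups
    ),
    file.path(dir, "meta.json"),
    auto_unbox = TRUE
  )
  invisible(dir)
}

#' Load a benchmark directory
#'
#' Reads back the files written by [writeBenchmark()] and validates their
#' referential integrity.
#'
#' @param dir benchmark directory.
#' @param threshold,direction binarization settings for raw affinity
#'   values (see [loadInteractions()]).
#' @return a list with `data`, `drugTree`, `targetTree`, `drugDistances`,
#'   `targetDistances`.
#' @export
loadBenchmark <- function(dir, threshold = 3, direction = "ge") {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  it <- loadInteractions(file.path(dir, "interactions.tsv"), threshold, direction)
  Fd <- loadFeatures(file.path(dir, "drug_features.tsv"))
  Ft <- loadFeatures(file.path(dir, "target_features.tsv"))
  drugTree <- parseHierarchy(
    file.path(dir, "drug_hierarchy.tsv"),
    kind = meta$drugKind, specialGroups = meta$drugSpecialGroups
  )
  targetTree <- parseHierarchy(
    file.path(dir, "target_hierarchy.tsv"),
    kind = meta$targetKind, specialGroups = meta$targetSpecialGroups
  )
  data <- dtiDataset(it, Fd, Ft, threshold, direction)
  distFor <- function(tree) {
    if (tree@kind == "graph") hopDistanceMatrix(tree) else lcaDistanceMatrix(tree)
  }
  list(
    data = data, drugTree = drugTree, targetTree = targetTree,
    drugDistances = distFor(drugTree), targetDistances = distFor(targetTree)
  )
}

#' Export a hierarchy distance matrix as TSV
#'
#' Header row of entity ids, one labeled row per entity.
#'
#' @param dm a [HierarchyDistanceMatrix-class].
#' @param file output path.
#' @export
writeDistanceMatrix <- function(dm, file) {
  df <- data.frame(id = dm@entities, dm@D, check.names = FALSE)
  colnames(df) <- c("id", dm@entities)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
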