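#' Neuron annotation tables
#'
#' Per-neuron developmental and anatomical labels: neuroblast lineage (e.g.
#' NB5-2), hemilineage (`dorsal`, `ventral`, `glial` or `unassigned`),
#' temporal group (1-4 or `NA` for unassigned), hemisegment (`left`/`right`),
#' `homolog_id` shared by a bilateral homolog pair (or `NA`), and cell class
#' (`interneuron`, `motor`, `sensory`). Validation enforces that homolog
#' pairs sit in opposite hemisegments and carry identical lineage and
#' hemilineage labels.
#'
#' @param df data frame with columns `neuron_id`, `lineage`, `hemilineage`,
#'   `temporal_group`, `hemisegment`, `homolog_id`, `cell_class`.
#' @return an `annotation_table` (a validated data frame keyed by neuron id).
#' @export
annotation_table <- function(df) {
  required <- c("neuron_id", "lineage", "hemilineage", "temporal_group",
                "hemisegment", "homolog_id", "cell_class")
  stopifnot(is.data.frame(df), all(required %in% names(df)))
  df <- df[required]
  df$neuron_id <- as.character(df$neuron_id)
  if (anyDuplicated(df$neuron_id)) stop("duplicated neuron ids in annotations")
  df$lineage <- as.character(df$lineage)
  hl_levels <- c("dorsal", "ventral", "glial", "unassigned")
  if (!all(df$hemilineage %in% hl_levels))
    stop("hemilineage must be one of: ", paste(hl_levels, collapse = ", "))
  tg <- suppressWarnings(as.integer(df$temporal_group))
  if (!all(is.na(tg) | tg %in% 1:4))
    stop("temporal_group must be 1-4 or NA")
  df$temporal_group <- tg
  if (!all(df$hemisegment %in% c("left", "right")))
    stop("hemisegment must be 'left' or 'right'")
  df$homolog_id <- as.character(df$homolog_id)
  df$homolog_id[df$homolog_id %in% c("", "NA")] <- NA_character_
  if (!all(df$cell_class %in% c("interneuron", "motor", "sensory")))
    stop("cell_class must be interneuron, motor or sensory")
  paired <- df[!is.na(df$homolog_id), , drop = FALSE]
  if (nrow(paired)) {
    for (h in unique(paired$homolog_id)) {
      p <- paired[paired$homolog_id == h, , drop = FALSE]
      if (nrow(p) != 2 || length(unique(p$hemisegment)) != 2)
        stop("homolog pair ", h, " must have one left and one right member")
      if (length(unique(p$lineage)) != 1 || length(unique(p$hemilineage)) != 1)
        stop("homolog pair ", h, " has mismatched lineage or hemilineage")
    }
  }
  rownames(df) <- NULL
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Read or write an annotation table as CSV
#'
#' @param path CSV file path.
#' @return `read_annotation_table()` returns an `annotation_table`.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) stop("annotation CSV does not exist: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(neuron_id = "character",
                                       homolog_id = "character"))
  annotation_table(df)
}

#' @rdname read_annotation_table
#' @param annotations an `annotation_table`.
#' @export
write_annotation_table <- function(annotations, path) {
  stopifnot(inherits(annotations, "annotation_table"))
  utils::write.csv(as.data.frame(annotations), path, row.names = FALSE)
  invisible(path)
}

#' Hemilineage-temporal cohort labels
#'
#' Builds the HL-T cohort label of every annotated neuron, e.g.
#' `"NB1_dorsal_T2_left"`; neurons with an unassigned hemilineage or
#' temporal group get `NA`.
#'
#' @param annotations an `annotation_table`.
#' @param by_hemisegment include the hemisegment in the label (left and
#'   right members of a cohort then form separate cohorts)?
#' @return character vector of labels named by neuron id.
#' @export
hlt_cohort <- function(annotations, by_hemisegment = TRUE) {
  a <- annotations
  lab <- paste(a$lineage, a$hemilineage, paste0("T", a$temporal_group),
               sep = "_")
  if (by_hemisegment) lab <- paste(lab, a$hemisegment, sep = "_")
  lab[is.na(a$temporal_group) | a$hemilineage %in% c("glial", "unassigned")] <-
    NA_character_
  names(lab) <- a$neuron_id
  lab
}
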