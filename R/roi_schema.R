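#' ROI schema
#'
#' An ROI schema fixes the node set of every network in an analysis: an
#' ordered vector of unique ROI labels, a hemisphere tag per label, and
#' named region sets (label subsets) used for modularization scoring.
#'
#' @param labels character vector of unique ROI names; their order is the
#'   node order of every matrix built against this schema.
#' @param hemisphere character vector, same length as `labels`, each entry
#'   one of `"left"`, `"right"`, `"midline"`.
#' @param region_sets named list of character vectors, each a subset of
#'   `labels` (e.g. a memory system or a reward-motivation system).
#' @return An object of class `roi_schema`.
#' @seealso [default_roi_schema()]
#' @export
roi_schema <- function(labels, hemisphere = rep("midline", length(labels)),
                       region_sets = list()) {
  labels <- as.character(labels)
  if (anyDuplicated(labels))
    stop("ROI labels must be unique; duplicated: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (length(hemisphere) != length(labels))
    stop("hemisphere must have one entry per label")
  hemisphere <- as.character(hemisphere)
  bad <- setdiff(unique(hemisphere), c("left", "right", "midline"))
  if (length(bad))
    stop("hemisphere entries must be left/right/midline; got: ",
         paste(bad, collapse = ", "))
  if (!is.list(region_sets))
    stop("region_sets must be a named list of label subsets")
  if (length(region_sets) && is.null(names(region_sets)))
    stop("region_sets must be named")
  for (nm in names(region_sets)) {
    extra <- setdiff(region_sets[[nm]], labels)
    if (length(extra))
      stop("region set '", nm, "' contains unknown labels: ",
           paste(extra, collapse = ", "))
  }
  structure(list(labels = labels,
                 hemisphere = hemisphere,
                 region_sets = lapply(region_sets, as.character)),
            class = "roi_schema")
}

#' Default 32-node bilateral rat brain schema
#'
#' Sixteen bilateral regions (frontal association, medial prefrontal,
#' orbitofrontal, anterior cingulate, insular, auditory, visual,
#' somatosensory, parietal association, retrosplenial and entorhinal
#' cortices; anterodorsal and posteroventral hippocampus; thalamus;
#' caudoputamen; amygdala), left/right, giving 32 ROIs. Two region sets are
#' predefined: `memory` (bilateral ADH, PVH, RSC, THA, INS) and
#' `reward_motivation` (bilateral CP, mPFC, ACC). The exact parcellation used
#' with a given atlas should be supplied by the user via [read_roi_schema()];
#' this default is a realistically named stand-in with the documented
#' region-set structure.
#'
#' @return An `roi_schema` with 32 labels.
#' @export
default_roi_schema <- function() {
  base <- c("FAC", "mPFC", "OFC", "ACC", "INS", "AC", "VC", "SsC",
            "ParA", "RSC", "ENT", "ADH", "PVH", "THA", "CP", "AMY")
  labels <- as.vector(t(outer(base, c("_L", "_R"), paste0)))
  hemisphere <- rep(c("left", "right"), times = length(base))
  bilat <- function(x) as.vector(t(outer(x, c("_L", "_R"), paste0)))
  roi_schema(labels, hemisphere,
             region_sets = list(
               memory = bilat(c("ADH", "PVH", "RSC", "THA", "INS")),
               reward_motivation = bilat(c("CP", "mPFC", "ACC")),
               left_cortex = paste0(c("FAC", "mPFC", "OFC", "ACC", "INS",
                                      "AC", "VC", "SsC", "ParA", "RSC",
                                      "ENT"), "_L"),
               right_cortex = paste0(c("FAC", "mPFC", "OFC", "ACC", "INS",
                                       "AC", "VC", "SsC", "ParA", "RSC",
                                       "ENT"), "_R")))
}

#' @export
print.roi_schema <- function(x, ...) {
  cat("ROI schema:", length(x$labels), "ROIs (",
      sum(x$hemisphere == "left"), "left /",
      sum(x$hemisphere == "right"), "right /",
      sum(x$hemisphere == "midline"), "midline )\n")
  if (length(x$region_sets))
    cat("region sets:",
        paste(sprintf("%s (%d)", names(x$region_sets),
                      lengths(x$region_sets)), collapse = ", "), "\n")
  invisible(x)
}

#' Resolve a region set argument to labels
#'
#' Accepts either the name of a region set in the schema or a character
#' vector of labels, and returns the validated label vector.
#' @param schema an `roi_schema`.
#' @param region_set a set name or character vector of labels.
#' @return character vector of labels.
#' @keywords internal
resolve_region_set <- function(schema, region_set) {
  stopifnot(inherits(schema, "roi_schema"))
  if (length(region_set) == 1L && region_set %in% names(schema$region_sets))
    return(schema$region_sets[[region_set]])
  unknown <- setdiff(region_set, schema$labels)
  if (length(unknown))
    stop("unknown ROI labels in region set: ", paste(unknown, collapse = ", "))
  as.character(region_set)
}

#' Read / write an ROI schema
#'
#' JSON files hold `labels`, `hemisphere` and `region_sets` directly. CSV
#' files have columns `label`, `hemisphere` and `region_sets`, the last a
#' `;`-separated list of set names the ROI belongs to (empty for none).
#'
#' @param path file path; format chosen by extension (`.json` else CSV).
#' @return An `roi_schema`.
#' @export
read_roi_schema <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
    rs <- x$region_sets
    if (is.null(rs)) rs <- list()
    return(roi_schema(x$labels, x$hemisphere, as.list(rs)))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("label", "hemisphere")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("schema file missing columns: ",
                         paste(miss, collapse = ", "))
  sets <- list()
  if ("region_sets" %in% names(df)) {
    tags <- strsplit(ifelse(is.na(df$region_sets), "", df$region_sets), ";")
    for (i in seq_along(tags))
      for (s in trimws(tags[[i]]))
        if (nzchar(s)) sets[[s]] <- c(sets[[s]], df$label[i])
  }
  roi_schema(df$label, df$hemisphere, sets)
}

#' @rdname read_roi_schema
#' @param schema an `roi_schema` to write.
#' @export
write_roi_schema <- function(schema, path) {
  stopifnot(inherits(schema, "roi_schema"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(labels = schema$labels,
                              hemisphere = schema$hemisphere,
                              region_sets = schema$region_sets),
                         path, auto_unbox = FALSE, pretty = TRUE)
  } else {
    tag <- vapply(schema$labels, function(l) {
      paste(names(schema$region_sets)[vapply(schema$region_sets,
                                             function(s) l %in% s, logical(1))],
            collapse = ";")
    }, character(1))
    utils::write.csv(data.frame(label = schema$labels,
                                hemisphere = schema$hemisphere,
                                region_sets = tag),
                     path, row.names = FALSE)
  }
  invisible(path)
}
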