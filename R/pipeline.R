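#' Analysis configuration
#'
#' Bundles everything [run_full_analysis()] needs: the cohort (a
#' [cohort_config()] to simulate, or a named list of CSV paths
#' `"<group>.<age>"` to load), the schema, the contrast list, GMS and
#' statistics options, and the output directory.
#'
#' Each contrast is `list(parameter =, type =, group = / age =, ...)`:
#' `type = "paired"` compares the two ages within one `group` (exhaustive
#' sign-flip over the subject pairs); `type = "unpaired"` compares the two
#' groups at one `age` (sampled label shuffles). The two-strain,
#' two-age paired design is enforced: no other comparison shape is
#' accepted. `parameter` is any statistic registered in [network_stat()]
#' (with `region_set` / `pair` where required).
#'
#' @param cohort a `cohort_config`, or named list of subject-table paths.
#' @param schema an `roi_schema`.
#' @param contrasts list of contrast specifications (see Details);
#'   `default_contrasts()` gives the study's standard set.
#' @param n_perm shuffles for unpaired contrasts.
#' @param q FDR target for the contrast family.
#' @param seed integer seed for all sampled randomness.
#' @param gms_mode,gms_adjacency,gms_convention GMS options.
#' @param out_dir output directory (created if missing).
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(cohort = default_cohort_config(),
                            schema = default_roi_schema(),
                            contrasts = default_contrasts(),
                            n_perm = 1000L, q = 0.05, seed = 1L,
                            gms_mode = "filtration",
                            gms_adjacency = "nonbacktracking",
                            gms_convention = "directed2",
                            out_dir = "metanet_out") {
  groups <- if (inherits(cohort, "cohort_config")) cohort$groups
            else unique(sub("\\..*$", "", names(cohort)))
  ages <- if (inherits(cohort, "cohort_config")) cohort$ages
          else unique(sub("^.*\\.", "", names(cohort)))
  for (ct in contrasts) {
    if (!ct$type %in% c("paired", "unpaired"))
      stop("contrast type must be 'paired' or 'unpaired'")
    if (ct$type == "paired" && (is.null(ct$group) || !ct$group %in% groups))
      stop("paired contrasts compare the two ages within one group; ",
           "specify group in ", paste(groups, collapse = "/"))
    if (ct$type == "unpaired" && (is.null(ct$age) || !ct$age %in% ages))
      stop("unpaired contrasts compare the two groups at one age; ",
           "specify age in ", paste(ages, collapse = "/"))
  }
  structure(list(cohort = cohort, schema = schema, contrasts = contrasts,
                 n_perm = as.integer(n_perm), q = q, seed = as.integer(seed),
                 gms_mode = gms_mode, gms_adjacency = gms_adjacency,
                 gms_convention = gms_convention, out_dir = out_dir,
                 groups = groups, ages = ages),
            class = "analysis_config")
}

#' @rdname analysis_config
#' @param groups,ages group and age names matching the cohort.
#' @export
default_contrasts <- function(groups = c("control", "adhd"),
                              ages = c("wk4", "wk6")) {
  c(lapply(groups, function(g)
      list(parameter = "gcc_threshold", type = "paired", group = g)),
    lapply(groups, function(g)
      list(parameter = "global_efficiency", type = "paired", group = g)),
    lapply(groups, function(g)
      list(parameter = "modularization", type = "paired", group = g,
           region_set = "memory")),
    lapply(groups, function(g)
      list(parameter = "modularization", type = "paired", group = g,
           region_set = "reward_motivation")),
    lapply(ages, function(a)
      list(parameter = "global_efficiency", type = "unpaired", age = a)))
}

contrast_label <- function(ct) {
  extra <- if (!is.null(ct$region_set)) paste0("_", ct$region_set)
           else if (!is.null(ct$pair)) paste0("_", paste(ct$pair, collapse = "-"))
           else ""
  paste0(ct$parameter, extra, "_", ct$type, "_",
         if (ct$type == "paired") ct$group else ct$age)
}

#' Run the full study-replica analysis
#'
#' Simulates (or loads) the four (group x age) subject tables; per cell
#' builds the positive-correlation network and writes the distance matrix
#' (CSV + GraphML), beta0-curve, SLM, Newick dendrogram, MST edge list and
#' modularization scores, GMS capacities and global efficiency; then runs
#' every configured contrast (exhaustive paired across ages within group,
#' sampled unpaired across groups within age), applies Benjamini-Hochberg
#' over the contrast family, and writes a manifest with versions, seeds and
#' the configuration hash. Rerunning with the same configuration and seeds
#' reproduces every numeric output byte for byte.
#'
#' @param config an [analysis_config()].
#' @return Invisibly, a list with the per-cell features, contrast table and
#'   manifest.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  schema <- config$schema
  mats <- if (inherits(config$cohort, "cohort_config")) {
    generate_roi_activity(config$cohort, schema)
  } else {
    lapply(config$cohort, read_subject_matrix, schema = schema)
  }
  cells <- names(mats)
  stage <- function(what, cell, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", what, "' failed for ", cell, ": ",
           conditionMessage(e)))
  }
  features <- list()
  files <- character(0)
  put <- function(f) { files <<- c(files, f); f }
  for (cell in cells) {
    m <- mats[[cell]]
    d <- stage("network", cell, distance_matrix(m))
    dend <- stage("filtration", cell, single_linkage_merges(d))
    t <- stage("mst", cell, minimum_spanning_tree(d))
    gms <- stage("gms", cell,
                 gms_analysis(d, mode = config$gms_mode,
                              adjacency = config$gms_adjacency,
                              convention = config$gms_convention))
    pre <- file.path(config$out_dir, cell)
    put(write_subject_matrix(m, paste0(pre, "_subjects.csv")))
    put(write_square_matrix(d, paste0(pre, "_distance.csv")))
    put(write_graphml(d, paste0(pre, "_network.graphml")))
    put(write_beta0_curve(beta0_curve(dend), paste0(pre, "_beta0.csv")))
    put(write_square_matrix(single_linkage_matrix(dend),
                            paste0(pre, "_slm.csv")))
    dendrogram_to_newick(dend, put(paste0(pre, "_dendrogram.nwk")))
    put(write_mst(t, paste0(pre, "_mst.tsv")))
    put(write_gms_json(gms, paste0(pre, "_gms.json")))
    scores <- lapply(schema$region_sets, function(s)
      modularization_score(t, s, warn_ties = FALSE))
    features[[cell]] <- list(
      gcc_threshold = gcc_threshold(dend),
      global_efficiency = global_efficiency(d),
      volume_entropy = gms$h,
      modularization = scores)
    jsonlite::write_json(features[[cell]],
                         put(paste0(pre, "_features.json")),
                         auto_unbox = TRUE, digits = 10)
  }
  contrast_rows <- NULL
  if (length(config$contrasts)) {
    res <- list()
    for (k in seq_along(config$contrasts)) {
      ct <- config$contrasts[[k]]
      sf <- network_stat(ct$parameter, schema, region_set = ct$region_set,
                         pair = ct$pair, gms_mode = config$gms_mode,
                         gms_adjacency = config$gms_adjacency)
      lab <- contrast_label(ct)
      pr <- if (ct$type == "paired") {
        a <- mats[[paste(ct$group, config$ages[2], sep = ".")]]
        b <- mats[[paste(ct$group, config$ages[1], sep = ".")]]
        stage("paired contrast", lab,
              paired_permutation_test(sf, unclass(a), unclass(b)))
      } else {
        a <- mats[[paste(config$groups[2], ct$age, sep = ".")]]
        b <- mats[[paste(config$groups[1], ct$age, sep = ".")]]
        stage("unpaired contrast", lab,
              unpaired_permutation_test(sf, unclass(a), unclass(b),
                                        n_perm = config$n_perm,
                                        seed = config$seed + k))
      }
      put(write_perm_json(pr, file.path(config$out_dir,
                                        paste0("contrast_", lab, ".json"))))
      res[[lab]] <- pr
    }
    fdr <- benjamini_hochberg(vapply(res, `[[`, numeric(1), "p_two_tailed"),
                              q = config$q)
    contrast_rows <- data.frame(
      contrast = names(res),
      observed = vapply(res, `[[`, numeric(1), "observed"),
      p = fdr$pvalues, p_bh = fdr$adjusted, rejected = fdr$rejected,
      n_permutations = vapply(res, `[[`, numeric(1), "n_permutations"),
      exhaustive = vapply(res, `[[`, logical(1), "exhaustive"),
      row.names = NULL)
    utils::write.csv(contrast_rows,
                     put(file.path(config$out_dir, "contrasts_fdr.csv")),
                     row.names = FALSE)
  }
  cfg_path <- file.path(config$out_dir, "config.json")
  jsonlite::write_json(serializable_config(config), cfg_path,
                       auto_unbox = TRUE, digits = 12, pretty = TRUE)
  manifest <- list(
    package = "metanet",
    package_version = as.character(utils::packageVersion("metanet")),
    r_version = R.version.string,
    seed = config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    cells = cells,
    n_contrasts = length(config$contrasts),
    files = basename(files))
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(features = features, contrasts = contrast_rows,
                 manifest = manifest))
}

serializable_config <- function(config) {
  list(cohort = if (inherits(config$cohort, "cohort_config"))
         unclass(config$cohort) else config$cohort,
       schema_labels = config$schema$labels,
       contrasts = config$contrasts,
       n_perm = config$n_perm, q = config$q, seed = config$seed,
       gms = list(mode = config$gms_mode, adjacency = config$gms_adjacency,
                  convention = config$gms_convention))
}

#' Export a distance network as GraphML
#' @param d a `distance_matrix`.
#' @param path output path.
#' @export
write_graphml <- function(d, path) {
  labs <- rownames(d)
  idx <- which(upper.tri(d) & is.finite(unclass(d)), arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = labs[idx[, 1]], to = labs[idx[, 2]],
               weight = unclass(d)[idx]),
    directed = FALSE, vertices = labs)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
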