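#' Default pipeline configuration
#'
#' Merges user settings over the defaults; all rule thresholds default to
#' the published values (15-node twigs, 2500 nm / 80 nm fragment bounds, 1%
#' connector density per nm, factor 2.5, 5000 nm distal trim, > 15 CX
#' synapses, > 5 strongest single connection). Unknown keys are rejected so
#' config typos fail loudly.
#'
#' @param config A named list, or a path to a YAML file with the same
#'   structure.
#' @return The completed configuration list.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    swc_dir = NULL, synapses = NULL, compartments = NULL, bundles = NULL,
    out_dir = NULL,
    swc_units = "nm", voxel_size_nm = 1,
    backbone = list(), cx_filter = list(),
    relabel_compartments = FALSE,
    split_hemilineages = FALSE,
    ecdf_region = NULL,
    torus_region = "EB",
    torus_axis = NULL,    # list(center, axis, ring_radius) to skip fitting
    projection_bins = 20,
    seed = 1L
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L) {
    stop("unknown pipeline config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  for (f in c("swc_dir", "synapses", "compartments", "bundles", "out_dir")) {
    if (is.null(cfg[[f]])) stop("pipeline config is missing '", f, "'")
  }
  cfg
}

#' Run the full lineage-annotation pipeline
#'
#' Stages: read inputs (SWC skeletons, synapse CSV, compartment JSON,
#' bundle JSON) -> backbone extraction + lineage assignment -> CX
#' large-field filter -> lineage-by-compartment counts, lineage-level
#' connection matrix (raw and max-normalised), lateral input fractions,
#' pairwise-strength ECDF, and the EB circular projection with density
#' profiles. All tables are written as CSV under `out_dir` together with a
#' JSON manifest recording parameters and MD5 hashes of every input and
#' output, so a re-run on identical inputs is byte-identical. A stage
#' failure removes partial outputs and reports the stage name.
#'
#' @param config See [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`catalog`,
#'   `filtered`, `counts`, `matrix`, `normalized`, `fractions`, `ecdf`,
#'   `projection`, `manifest`).
#' @export
run_pipeline <- function(config) {
  cfg <- pipeline_config(config)
  out <- cfg$out_dir
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(out, recursive = TRUE)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  for (d in c("catalog", "matrices", "spatial", "report")) {
    dir.create(file.path(out, d), recursive = TRUE, showWarnings = FALSE)
  }

  # --- io -------------------------------------------------------------------
  inputs <- stage("io", {
    list(skeletons = read_swc_dir(cfg$swc_dir, units = cfg$swc_units,
                                  voxel_size_nm = cfg$voxel_size_nm),
         connectors = read_synapse_table(cfg$synapses),
         model = read_compartments(cfg$compartments),
         bundles = read_bundles(cfg$bundles))
  })
  connectors <- inputs$connectors
  model <- inputs$model
  if (cfg$relabel_compartments || anyNA(connectors$compartment)) {
    connectors <- stage("label_compartments",
                        label_compartments(connectors, model,
                                           overwrite = cfg$relabel_compartments))
  }

  # --- backbone + lineage assignment ---------------------------------------
  bparams <- do.call(backbone_params, cfg$backbone)
  catalog <- stage("assign", {
    assign_lineages(inputs$skeletons, connectors, inputs$bundles,
                    params = bparams,
                    split_hemilineages = cfg$split_hemilineages)
  })

  # --- CX large-field filter ------------------------------------------------
  fparams <- do.call(cx_filter_params, cfg$cx_filter)
  filtered <- stage("filter",
                    filter_cx_largefield(catalog, connectors, fparams,
                                         model = model))

  # --- counts, matrices, fractions, ECDF -----------------------------------
  counts <- stage("counts", {
    count_by_lineage_and_compartment(filtered, connectors, model = model)
  })
  grouping <- stats::setNames(ifelse(is.na(catalog$lineage), "UNASSIGNED",
                                     catalog$lineage), catalog$neuron_id)
  cmat <- stage("matrix",
                build_connection_matrix(connectors, grouping, grouping))
  nmat <- stage("matrix", suppressWarnings(normalize_to_max(cmat)))
  fractions <- NULL
  ecdf_tab <- NULL
  if (nrow(filtered) > 0L) {
    tgt_grouping <- stats::setNames(filtered$lineage, filtered$neuron_id)
    tgt_grouping <- tgt_grouping[!is.na(tgt_grouping)]
    if (length(tgt_grouping) > 0L) {
      cx_names <- unlist(lapply(fparams$cx_regions, child_regions,
                                model = model))
      fractions <- stage("fractions", suppressWarnings(
        input_fraction_by_group(connectors, tgt_grouping,
                                exclude_regions = cx_names)))
    }
    ecdf_region <- cfg$ecdf_region
    if (!is.null(ecdf_region)) {
      ec <- stage("ecdf", pairwise_strength_ecdf(
        connectors, filtered$neuron_id,
        region = child_regions(ecdf_region, model)))
      if (ec$n_pairs > 0L) {
        xs <- sort(unique(ec$strengths))
        ecdf_tab <- data.frame(strength = xs, F = ec$ecdf(xs))
      }
    }
  }

  # --- EB circular projection -----------------------------------------------
  projection <- NULL
  if (!is.null(cfg$torus_region)) {
    tor_names <- child_regions(cfg$torus_region, model)
    rows <- connectors[!is.na(connectors$compartment) &
                         connectors$compartment %in% tor_names, ,
                       drop = FALSE]
    if (nrow(rows) >= 10L) {
      projection <- stage("projection", {
        axis_model <- if (!is.null(cfg$torus_axis)) {
          torus_axis_model(cfg$torus_axis$center, cfg$torus_axis$axis,
                           cfg$torus_axis$ring_radius)
        } else {
          fit_torus_axis(as.matrix(rows[, c("x", "y", "z")]))
        }
        proj <- circular_project(as.matrix(rows[, c("x", "y", "z")]),
                                 axis_model, weight = rows$weight)
        list(model = axis_model, projected = proj,
             density_u = density_profile(proj, "u", cfg$projection_bins),
             density_v = density_profile(proj, "v", cfg$projection_bins))
      })
    }
  }

  # --- write report ---------------------------------------------------------
  paths <- stage("write", {
    p <- character(0)
    wcsv <- function(obj, rel, rownames = FALSE) {
      fp <- file.path(out, rel)
      utils::write.csv(obj, fp, row.names = rownames)
      p[[length(p) + 1L]] <<- fp
      fp
    }
    wcsv(catalog, "catalog/catalog.csv")
    wcsv(filtered, "catalog/catalog_filtered.csv")
    wcsv(as.data.frame(counts), "report/lineage_by_compartment.csv",
         rownames = TRUE)
    wcsv(as.data.frame(unclass(cmat)), "matrices/connection_matrix.csv",
         rownames = TRUE)
    wcsv(as.data.frame(unclass(nmat)),
         "matrices/connection_matrix_normalized.csv", rownames = TRUE)
    if (!is.null(fractions)) wcsv(fractions, "report/input_fractions.csv")
    if (!is.null(ecdf_tab)) wcsv(ecdf_tab, "report/ecdf.csv")
    if (!is.null(projection)) {
      wcsv(projection$projected, "spatial/projection.csv")
      wcsv(projection$density_u, "spatial/density_u.csv")
      wcsv(projection$density_v, "spatial/density_v.csv")
    }
    p
  })

  manifest <- stage("manifest", {
    inputs_files <- c(list.files(cfg$swc_dir, full.names = TRUE),
                      cfg$synapses, cfg$compartments, cfg$bundles)
    man <- list(
      parameters = list(backbone = unclass(bparams),
                        cx_filter = unclass(fparams),
                        swc_units = cfg$swc_units,
                        voxel_size_nm = cfg$voxel_size_nm),
      counts = list(neurons_in = length(inputs$skeletons),
                    neurons_assigned = sum(catalog$method != "UNASSIGNED"),
                    neurons_filtered = nrow(filtered),
                    synapses_in = sum(connectors$weight)),
      input_md5 = as.list(tools::md5sum(sort(inputs_files))),
      output_md5 = as.list(tools::md5sum(sort(unlist(paths))))
    )
    fp <- file.path(out, "manifest.json")
    jsonlite::write_json(man, fp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    man
  })

  invisible(list(catalog = catalog, filtered = filtered, counts = counts,
                 matrix = cmat, normalized = nmat, fractions = fractions,
                 ecdf = ecdf_tab, projection = projection,
                 manifest = manifest))
}

#' Adapt a neuPrint-style CSV export to pipeline inputs
#'
#' Maps a local connectome export directory into the package's data model:
#' `neurons.csv` (columns `bodyId`, `type`) becomes the neuron records,
#' `synapses.csv` (columns `bodyId_pre`, `bodyId_post`, `prePost`, `x`,
#' `y`, `z`, `roi`) becomes a [connector_table()] with voxel coordinates
#' scaled to nm, and any SWC files under `swc/` are read with the same
#' voxel multiplier. Nothing is fetched remotely. Schema mismatches report
#' the expected and found columns explicitly.
#'
#' @param dir Export directory.
#' @param voxel_size_nm Voxel edge length in nm (default 8, the isotropic
#'   EM grid of common hemibrain exports).
#' @return A list: `records` (data.frame `neuron_id`, `type_label`,
#'   `hemisphere`), `connectors`, `skeletons` (possibly empty list).
#' @export
hemibrain_export_adapter <- function(dir, voxel_size_nm = 8) {
  need <- function(path, required) {
    if (!file.exists(path)) stop("export file missing: ", path)
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    absent <- setdiff(required, names(df))
    if (length(absent) > 0L) {
      stop("schema mismatch in ", basename(path), ": missing column(s) ",
           paste(absent, collapse = ", "), "; found: ",
           paste(names(df), collapse = ", "))
    }
    df
  }
  neu <- need(file.path(dir, "neurons.csv"), c("bodyId", "type"))
  records <- data.frame(neuron_id = as.character(neu$bodyId),
                        type_label = neu$type,
                        hemisphere = "UNKNOWN", stringsAsFactors = FALSE)
  syn <- need(file.path(dir, "synapses.csv"),
              c("bodyId_pre", "bodyId_post", "prePost", "x", "y", "z",
                "roi"))
  kind <- toupper(syn$prePost)
  kind[kind == "PRE"] <- "TBAR"
  kind[kind == "POST"] <- "PSD"
  connectors <- connector_table(data.frame(
    synapse_id = sprintf("syn%07d", seq_len(nrow(syn))),
    pre = as.character(syn$bodyId_pre), post = as.character(syn$bodyId_post),
    kind = kind,
    x = syn$x * voxel_size_nm, y = syn$y * voxel_size_nm,
    z = syn$z * voxel_size_nm,
    compartment = syn$roi, weight = 1L, stringsAsFactors = FALSE))
  skeletons <- list()
  if (dir.exists(file.path(dir, "swc"))) {
    skeletons <- read_swc_dir(file.path(dir, "swc"),
                              voxel_size_nm = voxel_size_nm)
  }
  list(records = records, connectors = connectors, skeletons = skeletons)
}
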