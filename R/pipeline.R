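#' Load descriptor sphere definitions from a YAML config
#'
#' Schema: a list under `descriptors`, each entry with `name`,
#' `radius_A`, `property` and an `anchor` (type `atom` or `centroid`
#' with `atoms` and optionally `residues` selectors resolved against the
#' reference ligand / receptor).
#'
#' @param path YAML file.
#' @param reference_complex `agstruct` to resolve anchors against.
#' @param ligand_res_name reference ligand residue name.
#' @return list of [pharmacophore_sphere()].
#' @export
load_descriptor_config <- function(path, reference_complex,
                                   ligand_res_name = "ABA") {
  cfg <- yaml::read_yaml(path)
  lig <- select_residue(reference_complex, ligand_res_name)
  at <- reference_complex$atoms
  lapply(cfg$descriptors, function(d) {
    ctr <- if (!is.null(d$anchor$atoms)) {
      hit <- lig[lig$name %in% d$anchor$atoms, , drop = FALSE]
      if (nrow(hit) < length(d$anchor$atoms))
        stop("descriptor '", d$name, "': anchor atom not found", call. = FALSE)
      colMeans(struct_coords(hit))
    } else if (!is.null(d$anchor$residues)) {
      side <- at[at$res_seq %in% d$anchor$residues & !at$is_hetero &
                   !(at$name %in% c("N", "CA", "C", "O")) &
                   at$element != "H", , drop = FALSE]
      if (!nrow(side))
        stop("descriptor '", d$name, "': anchor residues not found",
             call. = FALSE)
      colMeans(struct_coords(side))
    } else stop("descriptor '", d$name, "': no anchor", call. = FALSE)
    pharmacophore_sphere(d$name, ctr, d$radius_A, d$property)
  })
}

#' Shipped five-substitution receptor preset
#'
#' The engineered receptor variant is defined by five pocket/beta-sheet
#' substitutions transferred from a more sensitive homolog.  The preset
#' file ships with the package and is read here.
#'
#' @param path preset YAML (defaults to the installed
#'   `extdata/cspyl1_5m.yaml`).
#' @return data.frame with columns res_seq, from, to, new_res_name.
#' @export
cspyl1_5m_preset <- function(path = system.file("extdata", "cspyl1_5m.yaml",
                                                package = "agscreen")) {
  cfg <- yaml::read_yaml(path)
  do.call(rbind, lapply(cfg$substitutions, function(s)
    data.frame(res_seq = s$res_seq, from = s$from, to = s$to,
               new_res_name = s$to, stringsAsFactors = FALSE)))
}

#' Run the full screening pipeline
#'
#' filter -> score -> rank on file inputs, writing stage outputs and a
#' JSON run manifest (inputs, resolved configuration, output checksums).
#' Deterministic: identical inputs and seed produce byte-identical TSV
#' outputs.
#'
#' @param library_sdf ligand library (SDF).
#' @param reference_pdb reference receptor-ligand complex (PDB).
#' @param poses_sdf docked poses of the filtered ligands (SDF); poses are
#'   scored as given, in the receptor frame.
#' @param out_dir output directory (created if needed).
#' @param ligand_res_name reference ligand residue name in the PDB.
#' @param criteria [filter_criteria()].
#' @param anchor_spec forwarded to [build_descriptors()].
#' @param rank_config [ranking_config()]; default combines the docking
#'   score with all sphere occupancies by rank sum.
#' @param top_n shortlist size (default 93, the published screen's
#'   shortlist).
#' @param sampler,spacing,points,seed occupancy sampler options.
#' @return list with paths and the stage results (`filter_counts`,
#'   `occupancy`, `ranked`, `top`).
#' @export
run_screen <- function(library_sdf, reference_pdb, poses_sdf, out_dir,
                       ligand_res_name = "ABA",
                       criteria = filter_criteria(), anchor_spec = list(),
                       rank_config = NULL, top_n = 93,
                       sampler = "grid", spacing = 0.2, points = 1e5,
                       seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(passed = file.path(out_dir, "passed.sdf"),
                filter_report = file.path(out_dir, "filter_report.tsv"),
                occupancy = file.path(out_dir, "occupancy.tsv"),
                ranked = file.path(out_dir, "ranked.tsv"),
                manifest = file.path(out_dir, "run_manifest.json"))
  stage <- "filter"
  res <- tryCatch({
    counts <- filter_library(library_sdf, criteria, sdf_out = paths$passed,
                             report_out = paths$filter_report)
    stage <- "score"
    ref <- read_pdb(reference_pdb)
    spheres <- build_descriptors(ref, ligand_res_name, anchor_spec)
    poses <- read_sdf(poses_sdf)
    occ <- score_poses(poses, spheres, sampler = sampler, spacing = spacing,
                       points = points,
                       seed = if (sampler == "mc") seed else NULL)
    write_table(occ, paths$occupancy)
    stage <- "rank"
    if (is.null(rank_config)) {
      crits <- c(if (!all(is.na(occ$docking_score))) "docking_score",
                 grep("^occ_", names(occ), value = TRUE))
      rank_config <- ranking_config(crits)
    }
    ranked <- rank_poses(occ, rank_config)
    write_table(ranked, paths$ranked)
    top <- select_top(ranked, top_n)
    list(filter_counts = counts, occupancy = occ, ranked = ranked, top = top)
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  manifest <- list(
    package = "agscreen",
    version = as.character(utils::packageVersion("agscreen")),
    inputs = list(library_sdf = library_sdf, reference_pdb = reference_pdb,
                  poses_sdf = poses_sdf),
    config = list(criteria = unclass(criteria),
                  rank = list(criteria = rank_config$criteria,
                              weights = rank_config$weights,
                              aggregation = rank_config$aggregation),
                  sampler = sampler, spacing = spacing, points = points,
                  seed = seed, top_n = top_n,
                  ligand_res_name = ligand_res_name),
    outputs = lapply(paths[c("passed", "filter_report", "occupancy",
                             "ranked")],
                     function(p) list(path = p,
                                      md5 = unname(tools::md5sum(p)))),
    counts = list(read = res$filter_counts$read,
                  passed = res$filter_counts$passed,
                  poses_scored = nrow(res$occupancy),
                  top_selected = nrow(res$top)))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  c(res, list(paths = paths, manifest = manifest))
}
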