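# End-to-end orchestration: simulate (or load) inputs, compute membership
# probabilities, infer origins, and write the report bundle (presence matrix,
# origin and gain/loss tables, retention sums, core-family lists, ordered
# CDT, JSON manifest). All randomness flows from one seed; identical config
# and seed give byte-identical outputs.

#' Build a validated pipeline configuration
#'
#' Thresholds default to the standard analysis settings: search E-value
#' ceiling 1e-5, ECDF floor 1e-200, 10% fractional presence rule, per-species
#' core threshold 10%, decontamination at 96% identity / 90 bases / read
#' ratio 10 / read floor 10,000, FPKM noise threshold 0.01, k-mer window 13.
#'
#' @param out_dir Output directory for the report bundle.
#' @param seed Integer seed driving every stochastic step.
#' @param simulate If TRUE, inputs are generated with the demonstration
#'   preset; otherwise \code{hits}, \code{groups}, \code{newick} and
#'   \code{config} paths must be supplied.
#' @param hits,groups,newick,config Input paths (when \code{simulate} is
#'   FALSE).
#' @param gains_per_stem,loss_prob,false_pos_rate Generator settings for the
#'   simulated preset.
#' @param e_max,floor,threshold_frac,core_threshold Analysis thresholds.
#' @param decontam_identity,decontam_length,decontam_ratio,decontam_floor
#'   Decontamination thresholds (recorded in the manifest).
#' @param fpkm_threshold,error_window QC thresholds (recorded in the
#'   manifest).
#' @return A \code{"run_config"} list.
#' @export
run_config <- function(out_dir, seed = 1, simulate = TRUE,
                       hits = NULL, groups = NULL, newick = NULL, config = NULL,
                       gains_per_stem = paperlike_gains(), loss_prob = 0.2,
                       false_pos_rate = 0,
                       e_max = 1e-5, floor = 1e-200, threshold_frac = 0.10,
                       core_threshold = 0.10,
                       decontam_identity = 96, decontam_length = 90,
                       decontam_ratio = 10, decontam_floor = 10000,
                       fpkm_threshold = 0.01, error_window = 13) {
  stopifnot(e_max > 0, floor > 0, threshold_frac > 0, threshold_frac <= 1,
            core_threshold >= 0, core_threshold <= 1,
            decontam_identity >= 0, decontam_identity <= 100,
            decontam_length >= 1, decontam_ratio >= 1, decontam_floor >= 0,
            fpkm_threshold >= 0, error_window >= 2,
            loss_prob >= 0, loss_prob < 1,
            false_pos_rate >= 0, false_pos_rate <= 1)
  seed <- as.integer(seed)
  if (!simulate) {
    for (p in list(hits = hits, groups = groups, newick = newick,
                   config = config)) {
      if (is.null(p)) {
        stop("without simulate = TRUE, hits, groups, newick and config paths ",
             "are all required", call. = FALSE)
      }
    }
  }
  structure(list(out_dir = out_dir, seed = seed, simulate = simulate,
                 hits = hits, groups = groups, newick = newick, config = config,
                 gains_per_stem = gains_per_stem, loss_prob = loss_prob,
                 false_pos_rate = false_pos_rate,
                 e_max = e_max, floor = floor, threshold_frac = threshold_frac,
                 core_threshold = core_threshold,
                 decontam_identity = decontam_identity,
                 decontam_length = decontam_length,
                 decontam_ratio = decontam_ratio,
                 decontam_floor = decontam_floor,
                 fpkm_threshold = fpkm_threshold,
                 error_window = error_window),
            class = "run_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML path.
#' @param cfg A \code{"run_config"}.
#' @return \code{read_run_config} returns a \code{"run_config"};
#'   \code{write_run_config} returns \code{path} invisibly.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$gains_per_stem <- unlist(x$gains_per_stem)
  do.call(run_config, x)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  x <- unclass(cfg)
  x$gains_per_stem <- as.list(cfg$gains_per_stem)
  yaml::write_yaml(x[!vapply(x, is.null, TRUE)], path)
  invisible(path)
}

write_atomic <- function(writer, path) {
  tmp <- paste0(path, ".tmp")
  writer(tmp)
  file.rename(tmp, path)
  path
}

write_tsv <- function(df, path) {
  write_atomic(function(p) {
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }, path)
}

#' Run the full analysis pipeline
#'
#' With \code{simulate = TRUE} the demonstration inputs are generated, written
#' under \code{out_dir/inputs/} in their external formats (BLAST tabular,
#' groups file, Newick plus YAML config) and read back through the format
#' readers, so the run exercises the same code paths as a run on real files.
#' Results are written atomically under \code{out_dir/results/} together with
#' a JSON manifest recording the seed, every threshold used and the MD5 of
#' each output.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with the main in-memory results
#'   (\code{matrix}, \code{origins}, \code{gain_loss}, \code{retention},
#'   \code{core}, \code{order}) and \code{paths} of the written files.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  in_dir <- file.path(cfg$out_dir, "inputs")
  res_dir <- file.path(cfg$out_dir, "results")
  for (d in c(cfg$out_dir, in_dir, res_dir)) {
    dir.create(d, showWarnings = FALSE, recursive = TRUE)
  }
  paths <- list()

  if (cfg$simulate) {
    bundle <- simulate_paperlike(seed = cfg$seed,
                                 gains_per_stem = cfg$gains_per_stem,
                                 loss_prob = cfg$loss_prob,
                                 false_pos_rate = cfg$false_pos_rate)
    paths$hits <- write_atomic(function(p) write_blast_tab(bundle$hits, p),
                               file.path(in_dir, "allvall.blast.tsv"))
    paths$groups <- write_atomic(function(p) write_groups(bundle$catalog, p),
                                 file.path(in_dir, "groups.txt"))
    nwk <- file.path(in_dir, "tree.nwk"); ycf <- file.path(in_dir, "groups.yaml")
    write_tree_config(bundle$tree, nwk, ycf)
    paths$newick <- nwk; paths$config <- ycf
    paths$truth_origins <- write_tsv(bundle$truth$origins,
                                     file.path(in_dir, "truth_origins.tsv"))
  } else {
    paths$hits <- cfg$hits; paths$groups <- cfg$groups
    paths$newick <- cfg$newick; paths$config <- cfg$config
  }

  hits <- read_blast_tab(paths$hits)
  catalog <- read_groups(paths$groups)
  tree <- read_tree_config(paths$newick, paths$config)

  ref <- ecdf_reference_from_hits(hits, floor = cfg$floor)
  m <- presence_probabilities(catalog, hits, species = tree$phy$tip.label,
                              e_max = cfg$e_max, floor = cfg$floor, ref = ref)
  paths$matrix <- write_atomic(function(p) write_matrix(m, p),
                               file.path(res_dir, "presence_matrix.tsv"))

  origins <- infer_origins(m, tree, threshold_frac = cfg$threshold_frac)
  paths$origins <- write_tsv(origins, file.path(res_dir, "origins.tsv"))

  gl <- node_gain_loss(origins, m, tree, threshold_frac = cfg$threshold_frac)
  paths$gain_loss <- write_tsv(gl, file.path(res_dir, "node_gain_loss.tsv"))

  ret <- retention_sums(m, origins)
  ret_df <- data.frame(species = rownames(ret), ret, check.names = FALSE)
  paths$retention <- write_tsv(ret_df, file.path(res_dir, "retention.tsv"))

  core <- list()
  for (g in names(tree$major_groups)) {
    anc <- group_ancestor(tree, g)
    if (is.na(anc)) next
    fams <- origins$family[origins$origin == anc]
    core[[g]] <- core_families(m, tree$major_groups[[g]], families = fams,
                               threshold = cfg$core_threshold)
    paths[[paste0("core_", g)]] <- write_atomic(
      function(p) writeLines(core[[g]], p),
      file.path(res_dir, paste0("core_families_", g, ".txt")))
  }

  ord <- heatmap_order(m, tree, threshold_frac = cfg$threshold_frac)
  paths$order <- write_atomic(function(p) writeLines(ord, p),
                              file.path(res_dir, "heatmap_order.txt"))
  paths$cdt <- write_atomic(function(p) write_cdt(m, p, order = ord),
                            file.path(res_dir, "presence_ordered.cdt"))

  manifest <- list(
    seed = cfg$seed,
    thresholds = list(e_max = cfg$e_max, ecdf_floor = cfg$floor,
                      presence_fraction = cfg$threshold_frac,
                      core_threshold = cfg$core_threshold,
                      decontam = list(identity = cfg$decontam_identity,
                                      length = cfg$decontam_length,
                                      ratio = cfg$decontam_ratio,
                                      floor = cfg$decontam_floor),
                      fpkm = cfg$fpkm_threshold,
                      error_window = cfg$error_window),
    simulate = cfg$simulate,
    n_families = nrow(m), n_species = ncol(m),
    outputs = lapply(paths[c("matrix", "origins", "gain_loss", "retention",
                             "order", "cdt")],
                     function(p) unname(tools::md5sum(p)))
  )
  paths$manifest <- write_atomic(
    function(p) jsonlite::write_json(manifest, p, auto_unbox = TRUE,
                                     pretty = TRUE, digits = NA),
    file.path(res_dir, "manifest.json"))

  invisible(list(matrix = m, origins = origins, gain_loss = gl,
                 retention = ret, core = core, order = ord, paths = paths))
}
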