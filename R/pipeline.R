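#' Default pipeline configuration
#'
#' Returns the full configuration template with every parameter explicit,
#' so a run is self-documenting. Defaults: window 40 bp, step 1 bp,
#' 100 bootstrap replicates, clock rate 3.54 %/My, network epsilon 0.
#'
#' @param fasta path to an aligned FASTA file.
#' @param groups path to an id->group TSV, or a named character vector.
#' @param out_dir output directory.
#' @param seed RNG seed for all stochastic steps.
#' @return a named list understood by [run_pipeline()].
#' @export
pipeline_config <- function(fasta = NULL, groups = NULL,
                            out_dir = "crhaplo_out", seed = NULL) {
  list(
    input = list(fasta = fasta, groups = groups),
    params = list(window = 40L, step = 1L, bootstrap = 100L,
                  rate = 3.54, epsilon = 0L,
                  identity = "strict", resolve = "consensus",
                  metric = "t3p", seed = seed),
    out_dir = out_dir
  )
}

validate_config <- function(cfg) {
  p <- cfg$params
  stochastic <- isTRUE(p$bootstrap > 0L)
  if (stochastic && is.null(p$seed)) {
    stop("config validation: seed is required when bootstrap is enabled",
         call. = FALSE)
  }
  if (is.null(cfg$input$fasta)) {
    stop("config validation: input$fasta is required", call. = FALSE)
  }
  invisible(cfg)
}

#' Run the full control-region analysis pipeline
#'
#' Executes collapse -> site statistics -> sliding window -> group
#' distances -> diversity decomposition -> molecular clock -> median-
#' joining network on one aligned input, writing TSV summaries, network
#' files and a JSON run manifest (parameters, seed, counts) to the output
#' directory. Any stage failure aborts with the stage name.
#'
#' @param cfg configuration list (see [pipeline_config()]) or path to a
#'   YAML file with the same structure.
#' @return invisibly, a list with all stage results (`alignment`,
#'   `haplotypes`, `sites`, `profile`, `distances`, `diversity`,
#'   `clock`, `network`, `manifest`).
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg) && length(cfg) == 1L) cfg <- yaml::read_yaml(cfg)
  validate_config(cfg)
  p <- cfg$params
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  grp <- cfg$input$groups
  if (is.character(grp) && length(grp) == 1L && file.exists(grp)) {
    grp <- read_group_table(grp)
  }
  aln <- stage("read", read_fasta(cfg$input$fasta, groups = grp))

  sites <- stage("sitestats", classify_sites(aln))
  aln_res <- stage("resolve", resolve_ambiguities(
    aln, mode = p$resolve, scope = "pis", pis = sites$positions_PIS))
  haps <- stage("collapse", collapse_haplotypes(aln_res, identity = p$identity))
  utils::write.table(
    data.frame(haplotype = names(haps$haplotypes),
               multiplicity = haps$multiplicity,
               members = vapply(haps$members, paste, "", collapse = ",")),
    file.path(cfg$out_dir, "haplotypes.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  profile <- stage("window", sliding_window_Ss(aln_res, p$window, p$step))
  write_window_profile(profile, file.path(cfg$out_dir, "window_profile.tsv"))

  groups_present <- !is.null(aln$groups) && length(unique(aln$groups)) >= 2L
  dist_rows <- list(); diversity <- NULL; clock <- NULL
  if (groups_present) {
    gl <- unique(aln$groups)
    for (g in gl) {
      n_g <- sum(aln$groups == g)
      if (n_g < 2L) next
      dist_rows[[paste0("within_", g)]] <- stage("distances",
        group_mean_distance(haps, metric = p$metric, scope = "within",
                            groups = g, bootstrap = p$bootstrap,
                            seed = p$seed))
    }
    prs <- utils::combn(gl, 2L)
    for (k in seq_len(ncol(prs))) {
      dist_rows[[paste0("between_", prs[1L, k], "_", prs[2L, k])]] <-
        stage("distances",
          group_mean_distance(haps, metric = p$metric, scope = "between",
                              groups = prs[, k], bootstrap = p$bootstrap,
                              seed = p$seed))
    }
    dtab <- do.call(rbind, lapply(names(dist_rows), function(nm) {
      d <- dist_rows[[nm]]
      data.frame(comparison = nm, metric = d$metric,
                 mean_pct = d$mean, se_pct = d$se, n_pairs = d$n_pairs)
    }))
    utils::write.table(dtab, file.path(cfg$out_dir, "distances.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    sizes <- table(aln$groups)
    if (all(sizes >= 2L)) {
      diversity <- stage("diversity", nst_matrix(
        aln, bootstrap = p$bootstrap, seed = p$seed))
      write_nst_matrix(diversity, file.path(cfg$out_dir, "diversity_nst.tsv"))
    }
    first_between <- dist_rows[[grep("^between_", names(dist_rows))[1L]]]
    clock <- stage("clock", divergence_time(
      first_between$mean,
      ifelse(is.na(first_between$se), 0, first_between$se), rate = p$rate))
    utils::write.table(
      data.frame(distance_pct = clock$distance, se_pct = clock$se,
                 rate_pct_per_My = clock$rate,
                 time_ka = clock$time_ka, time_se_ka = clock$time_se_ka),
      file.path(cfg$out_dir, "clock.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  network <- NULL
  if (haps$H >= 2L) {
    network <- stage("network", build_mjn(haps, epsilon = p$epsilon))
    export_network(network, file.path(cfg$out_dir, "network.graphml"),
                   "graphml")
    export_network(network, file.path(cfg$out_dir, "network_edges.tsv"),
                   "tsv")
  }

  manifest <- list(
    package = "crhaplo",
    version = as.character(utils::packageVersion("crhaplo")),
    parameters = p,
    input = list(fasta = cfg$input$fasta,
                 n_sequences = length(aln$ids), length_bp = aln$length),
    results = list(H = haps$H, S = sites$S, PIS = sites$PIS,
                   n_windows = length(profile$starts),
                   n_median_vectors = if (is.null(network)) 0L else
                     sum(network$nodes$is_median)))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(alignment = aln, haplotypes = haps, sites = sites,
                 profile = profile, distances = dist_rows,
                 diversity = diversity, clock = clock, network = network,
                 manifest = manifest))
}
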