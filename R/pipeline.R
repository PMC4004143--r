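# End-to-end orchestration: simulate (or read) profiles, then diversity,
# divergence matrices, the two-group outlier scan, PCoA, rarefaction and
# (when coordinates exist) isolation by distance, each written as CSV with
# a provenance header. Deterministic given the run seed: one global seed is
# fanned out to fixed per-stage child seeds.

#' Pipeline run settings
#'
#' Exactly one of `sim` (a [sim_config()]) or `input` (a list with `sync`
#' path) must be given.
#'
#' @param out_dir Output directory (created if needed).
#' @param sim Optional [sim_config()] for simulated input.
#' @param input Optional list with `sync` (profile file path).
#' @param populations Population metadata table (see
#'   [load_population_table()]); optional for simulated input.
#' @param group_column Column of the population table defining the
#'   two-group comparison for the outlier scan (default
#'   `"cry3bb1_response"`, using its `"high"`/`"low"` levels), or `NULL`
#'   to skip the scan.
#' @param filter A [filter_config()].
#' @param scan A [scan_config()].
#' @param seed Integer master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, sim = NULL, input = NULL, populations = NULL,
                       group_column = "cry3bb1_response",
                       filter = filter_config(), scan = scan_config(),
                       seed = 1L) {
  if (is.null(sim) == is.null(input))
    stop("exactly one of sim or input must be given")
  structure(list(out_dir = out_dir, sim = sim, input = input,
                 populations = populations, group_column = group_column,
                 filter = filter, scan = scan, seed = as.integer(seed)),
            class = "run_config")
}

write_output_csv <- function(dt, path, seed, filter) {
  hdr <- c(sprintf("# poolscan %s", as.character(utils::packageVersion("poolscan"))),
           sprintf("# seed: %d", seed),
           sprintf("# filters: min_coverage=%d max_coverage=%d min_count=%d",
                   filter$min_coverage, filter$max_coverage, filter$min_count))
  writeLines(hdr, path)
  fwrite(dt, path, append = TRUE, col.names = TRUE)
  path
}

#' Run the full pooled-sequencing analysis pipeline
#'
#' Stages, in dependency order: profiles (simulated and written as sync, or
#' read from sync), per-unigene and per-population diversity with high-pi
#' outlier removal, pairwise pi_xy and F_ST matrices, the two-group
#' permutation outlier scan (when group labels are available), PCoA of the
#' pi_xy matrix, SNP rarefaction, and isolation by distance when
#' coordinates are available. Rerunning with the same configuration and
#' seed reproduces every output byte for byte.
#'
#' @param cfg A [run_config()].
#' @return Named list of output file paths (the manifest), invisibly.
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)
  child <- sample.int(.Machine$integer.max - 1L, 8L)
  manifest <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           "; partial outputs: ", paste(unlist(manifest), collapse = ", "),
           call. = FALSE))
  }

  # --- profiles
  profiles <- stage("profiles", {
    if (!is.null(cfg$sim)) {
      simcfg <- cfg$sim
      simcfg$seed <- child[1]
      sim <- simulate_metapopulation(simcfg)
      manifest$sync <- file.path(cfg$out_dir, "profiles.sync")
      write_sync(sim$profiles, manifest$sync)
      manifest$truth <- write_truth(sim$truth, cfg$out_dir)
      sim$profiles
    } else {
      read_sync(cfg$input$sync)
    }
  })
  pops <- unique(profiles$pop)
  pooln <- 10L
  if (!is.null(cfg$populations)) {
    pt <- as.data.table(cfg$populations)
    pooln <- setNames(pt$pool_chromosomes, pt$name)[pops]
    pooln[is.na(pooln)] <- 10L
  }

  # --- diversity
  manifest$pi_unigene <- stage("diversity", {
    st <- pi_unigene(profiles, pool_chromosomes = pooln, cfg = cfg$filter)
    kept <- drop_pi_outlier_unigenes(st)$kept
    p1 <- write_output_csv(st, file.path(cfg$out_dir, "pi_unigene.csv"),
                           cfg$seed, cfg$filter)
    manifest$pi_population <- write_output_csv(
      population_mean_pi(kept), file.path(cfg$out_dir, "pi_population.csv"),
      cfg$seed, cfg$filter)
    p1
  })

  # --- divergence matrices
  mx <- stage("divergence", {
    pixy_m <- pairwise_matrix(profiles, "pixy", cfg$filter, pooln)
    fst_m <- pairwise_matrix(profiles, "fst", cfg$filter, pooln)
    manifest$pixy_matrix <- write_output_csv(
      data.table(pop = rownames(pixy_m), pixy_m),
      file.path(cfg$out_dir, "pixy_matrix.csv"), cfg$seed, cfg$filter)
    manifest$fst_matrix <- write_output_csv(
      data.table(pop = rownames(fst_m), fst_m),
      file.path(cfg$out_dir, "fst_matrix.csv"), cfg$seed, cfg$filter)
    list(pixy = pixy_m, fst = fst_m)
  })

  # --- outlier scan
  groups <- NULL
  if (!is.null(cfg$group_column) && !is.null(cfg$populations)) {
    pt <- as.data.table(cfg$populations)
    lab <- setNames(as.character(pt[[cfg$group_column]]), pt$name)[pops]
    use <- lab %in% c("high", "low") | lab %in% c("TRUE", "FALSE")
    if (sum(use) >= 2 && length(unique(lab[use])) == 2)
      groups <- lab[use]
  } else if (!is.null(cfg$sim) && !is.null(cfg$sim$group_labels)) {
    gl <- cfg$sim$group_labels
    groups <- setNames(as.character(gl),
                       if (!is.null(names(gl))) names(gl) else pops)
  }
  if (!is.null(groups)) {
    manifest$scan <- stage("scan", {
      sc <- cfg$scan
      sc$seed <- child[2]
      res <- outlier_scan(profiles, groups, sc, cfg$filter)
      res[, note := "exploratory; no multiple-test correction"]
      write_output_csv(res, file.path(cfg$out_dir, "scan.csv"),
                       cfg$seed, cfg$filter)
    })
  }

  # --- structure
  manifest$pcoa <- stage("pcoa", {
    fit <- pcoa(mx$pixy, k = min(3L, length(pops) - 1L))
    write_output_csv(data.table(pop = rownames(fit$points), fit$points),
                     file.path(cfg$out_dir, "pcoa.csv"), cfg$seed, cfg$filter)
  })
  manifest$rarefaction <- stage("rarefaction", {
    rc <- rarefaction(snp_sets(profiles, cfg$filter), seed = child[3])
    write_output_csv(rc, file.path(cfg$out_dir, "rarefaction.csv"),
                     cfg$seed, cfg$filter)
  })
  if (!is.null(cfg$populations) &&
      all(c("lat", "lon") %in% names(cfg$populations))) {
    pt <- as.data.table(cfg$populations)
    cd <- pt[name %in% pops & !is.na(lat) & !is.na(lon)]
    if (nrow(cd) >= 4) {
      manifest$ibd <- stage("ibd", {
        keep <- cd$name
        r <- ibd(mx$fst[keep, keep], cd, seed = child[4])
        write_output_csv(
          data.table(pearson_r = r$pearson_r, mantel_p = r$mantel_p,
                     slope = r$slope, intercept = r$intercept,
                     n_pairs = r$n_pairs),
          file.path(cfg$out_dir, "ibd.csv"), cfg$seed, cfg$filter)
      })
    }
  }
  invisible(manifest)
}
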