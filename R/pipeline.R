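# Command-line pipeline: configuration, loci computation, occupancy report,
# and the Table-shaped convergence report. All stages are deterministic
# given the config and seed, and every output CSV carries a header comment
# recording version, seed and n_sim.

pkg_version <- function() as.character(utils::packageVersion("tetraconv"))

default_config <- function() {
  list(loci = NULL, spectra = NULL, species_table = NULL, tree = NULL,
       sensitivity = NULL, visual_system = "VS", illuminant = NULL,
       background = NULL, span = 0.25, unit = "fraction",
       n_sim = 999L, seed = 1L, alpha = 0.05, out_dir = ".",
       prune = FALSE, reconstruct_null = FALSE)
}

#' Read a run configuration file
#'
#' A flat `key: value` text format (YAML-like; `#` comments and blank lines
#' ignored). Unknown keys are rejected. Values for `n_sim`, `seed`, `alpha`
#' and `span` are numeric; `prune` and `reconstruct_null` are `true`/`false`.
#'
#' @param path config file path
#' @param overrides named list applied on top of the file values
#' @return config list with defaults filled in
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*:\\s*(.*)$", ln))[[1]]
      if (length(m) != 3L) stop("cannot parse config line: ", ln)
      key <- m[2]; val <- trimws(m[3])
      if (!key %in% names(cfg)) stop("unknown config key: ", key)
      cfg[[key]] <- val
    }
  }
  for (k in names(overrides)) {
    if (!k %in% names(cfg)) stop("unknown config key: ", k)
    cfg[[k]] <- overrides[[k]]
  }
  for (k in c("n_sim", "seed")) cfg[[k]] <- as.integer(cfg[[k]])
  for (k in c("alpha", "span")) cfg[[k]] <- as.numeric(cfg[[k]])
  for (k in c("prune", "reconstruct_null"))
    cfg[[k]] <- isTRUE(cfg[[k]]) || identical(tolower(as.character(cfg[[k]])), "true")
  if (cfg$n_sim < 1L) stop("n_sim must be >= 1")
  for (k in c("loci", "spectra", "species_table", "tree", "sensitivity",
              "illuminant", "background"))
    if (!is.null(cfg[[k]]) && !identical(cfg[[k]], "") && !file.exists(cfg[[k]]))
      stop("configured file does not exist: ", k, " = ", cfg[[k]])
  cfg
}

config_visual_system <- function(config) {
  if (!is.null(config$sensitivity))
    load_visual_system(config$sensitivity, name = config$visual_system)
  else
    packaged_visual_system(config$visual_system)
}

csv_header_comment <- function(config) {
  sprintf("# tetraconv %s | visual_system=%s seed=%d n_sim=%d",
          pkg_version(), config$visual_system, config$seed, config$n_sim)
}

write_report_csv <- function(df, path, config) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(csv_header_comment(config), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

read_loci_csv <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("species", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("loci table needs columns species,x,y,z")
  if (!"visitation" %in% names(df)) df$visitation <- NA_character_
  if (!"subgroup" %in% names(df)) df$subgroup <- NA_character_
  df[, c("species", "x", "y", "z", "visitation", "subgroup")]
}

#' Compute (or pass through) colour loci for a species set
#'
#' With `config$loci` set, the precomputed table is normalised and passed
#' through. Otherwise each column of the wide spectra CSV is smoothed,
#' de-negatived, resampled, and mapped to a locus under the configured
#' visual system, illuminant and background. A species table
#' (`species,visitation[,subgroup]`) is joined when provided.
#'
#' @param config a config list from [read_run_config()]
#' @return data.frame `species,x,y,z,visitation,subgroup` (also written to
#'   `out_dir/loci.csv`)
#' @export
cmd_loci <- function(config) {
  if (!is.null(config$loci)) {
    df <- read_loci_csv(config$loci)
  } else {
    if (is.null(config$spectra)) stop("config needs either loci or spectra")
    vs <- config_visual_system(config)
    illum <- if (!is.null(config$illuminant)) read_spectra(config$illuminant)[[1]]
             else packaged_spectrum("illuminant")
    bkg <- if (!is.null(config$background)) read_spectra(config$background)[[1]]
           else packaged_spectrum("background")
    specs <- read_spectra(config$spectra, unit = config$unit)
    rows <- lapply(specs, function(s) {
      sp <- process_spectrum(s, span = config$span)
      loc <- to_locus(quantum_catches(sp, vs, illum, bkg), vs, species = s$label)
      data.frame(species = s$label, x = loc$xyz[1], y = loc$xyz[2],
                 z = loc$xyz[3], stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
    rownames(df) <- NULL
    df$visitation <- NA_character_
    df$subgroup <- NA_character_
  }
  if (!is.null(config$species_table)) {
    st <- read.csv(config$species_table, comment.char = "#",
                   stringsAsFactors = FALSE)
    names(st) <- tolower(names(st))
    df$visitation <- st$visitation[match(df$species, st$species)]
    if ("subgroup" %in% names(st))
      df$subgroup <- st$subgroup[match(df$species, st$species)]
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_report_csv(df, file.path(config$out_dir, "loci.csv"), config)
  invisible(df)
}

loci_groups <- function(df) {
  list(all = df,
       insect = df[df$visitation %in% "insect", , drop = FALSE],
       bird_visited = df[df$visitation %in% c("bird", "both"), , drop = FALSE],
       bird_only = df[df$visitation %in% "bird", , drop = FALSE],
       bird_and_insect = df[df$visitation %in% "both", , drop = FALSE])
}

#' Morphospace occupancy report
#'
#' Per-group convex-hull volumes as absolute values and as percentages of
#' the tetrahedron volume, plus pairwise hull overlaps (as % of the first
#' group's volume and of the combined volume).
#'
#' @param config a config list (needs `loci` or the spectra inputs)
#' @param loci optional loci data.frame (skips [cmd_loci()])
#' @return list with data.frames `volumes` and `overlaps` (also written to
#'   `out_dir/occupancy.csv` and `out_dir/overlap.csv`)
#' @export
cmd_occupancy <- function(config, loci = NULL) {
  df <- if (is.null(loci)) cmd_loci(config) else loci
  vs <- config_visual_system(config)
  vt <- tetra_volume(vs)
  groups <- loci_groups(df)
  hulls <- lapply(groups, function(g)
    if (nrow(g) >= 4L) hull_volume(as.matrix(g[, c("x", "y", "z")])) else NULL)
  volumes <- do.call(rbind, lapply(names(groups), function(nm) {
    h <- hulls[[nm]]
    data.frame(group = nm, n = nrow(groups[[nm]]),
               volume = if (is.null(h)) NA_real_ else h$volume,
               pct_of_tetrahedron = if (is.null(h)) NA_real_
                                    else 100 * h$volume / vt,
               degenerate = is.null(h) || h$degenerate,
               stringsAsFactors = FALSE)
  }))
  pairs <- list(c("insect", "bird_visited"), c("insect", "bird_only"),
                c("insect", "bird_and_insect"))
  overlaps <- do.call(rbind, lapply(pairs, function(pr) {
    ha <- hulls[[pr[1]]]; hb <- hulls[[pr[2]]]
    if (is.null(ha) || is.null(hb) || ha$degenerate || hb$degenerate)
      return(data.frame(group_a = pr[1], group_b = pr[2],
                        overlap_volume = NA_real_, pct_of_a = NA_real_,
                        pct_of_union = NA_real_, stringsAsFactors = FALSE))
    ov <- overlap_fraction(ha, hb, mode = "exact")
    data.frame(group_a = pr[1], group_b = pr[2],
               overlap_volume = ov$overlap_volume,
               pct_of_a = 100 * ov$fraction_of_a,
               pct_of_union = 100 * ov$fraction_of_union,
               stringsAsFactors = FALSE)
  }))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_report_csv(volumes, file.path(config$out_dir, "occupancy.csv"), config)
  write_report_csv(overlaps, file.path(config$out_dir, "overlap.csv"), config)
  invisible(list(volumes = volumes, overlaps = overlaps))
}

match_tree_and_loci <- function(tree, df, prune) {
  in_tree_only <- setdiff(tree$tip.label, df$species)
  in_loci_only <- setdiff(df$species, tree$tip.label)
  if (length(in_tree_only) || length(in_loci_only)) {
    msg <- paste0("species mismatch between tree and loci; tree-only: ",
                  paste(in_tree_only, collapse = ", "), "; loci-only: ",
                  paste(in_loci_only, collapse = ", "))
    if (!prune) stop(msg, " (set prune to intersect)")
    warning(msg, " -- pruning to the intersection")
    if (length(in_tree_only)) tree <- ape::drop.tip(tree, in_tree_only)
    df <- df[df$species %in% tree$tip.label, , drop = FALSE]
  }
  list(tree = tree, loci = df)
}

convergence_targets <- function(df) {
  out <- list()
  for (grp in c("bird_visited", "bird_only", "bird_and_insect")) {
    members <- switch(grp,
                      bird_visited = df$visitation %in% c("bird", "both"),
                      bird_only = df$visitation %in% "bird",
                      bird_and_insect = df$visitation %in% "both")
    for (sub in c("all", "red_arm", "non_red_arm")) {
      sel <- members & switch(sub,
                              all = TRUE,
                              red_arm = df$subgroup %in% "red_arm",
                              non_red_arm = !(df$subgroup %in% "red_arm"))
      out[[paste(grp, sub, sep = ".")]] <-
        list(group = grp, subgroup = sub, species = df$species[sel])
    }
  }
  out
}

#' Convergence report over the standard target grid
#'
#' For each (visitation group x subgroup) target, builds the minimum
#' enclosing ellipsoid of the member loci and runs [convergence_test()]
#' against the full-sample tree and tip loci, then applies the Holm
#' correction table-wide. p-values are printed to 3 decimals in the CSV;
#' full precision goes to a JSON sidecar.
#'
#' @param config a config list (needs `tree` plus `loci` or spectra inputs)
#' @param loci optional loci data.frame
#' @return data.frame, one row per target (also written to
#'   `out_dir/convergence.csv` and `.json`)
#' @export
cmd_convergence <- function(config, loci = NULL) {
  if (is.null(config$tree)) stop("config needs a tree")
  df <- if (is.null(loci)) cmd_loci(config) else loci
  tree <- read_tree(config$tree)
  mt <- match_tree_and_loci(tree, df, config$prune)
  tree <- mt$tree; df <- mt$loci
  tips <- as.matrix(df[, c("x", "y", "z")])
  rownames(tips) <- df$species
  targets <- convergence_targets(df)
  rows <- list()
  for (nm in names(targets)) {
    tg <- targets[[nm]]
    pts <- tips[tg$species, , drop = FALSE]
    if (nrow(pts) < 4L) {
      rows[[nm]] <- data.frame(visual_system = config$visual_system,
                               group = tg$group, subgroup = tg$subgroup,
                               n_target = nrow(pts), observed = NA_integer_,
                               null_mean = NA_real_, null_sd = NA_real_,
                               null_max = NA_integer_, p = NA_real_,
                               note = "degenerate: <4 target species",
                               stringsAsFactors = FALSE)
      next
    }
    region <- min_ellipsoid(pts, on_degenerate = "flag")
    res <- convergence_test(tree, tips, region, n_sim = config$n_sim,
                            seed = config$seed,
                            reconstruct_null = config$reconstruct_null,
                            region_label = nm)
    rows[[nm]] <- data.frame(visual_system = config$visual_system,
                             group = tg$group, subgroup = tg$subgroup,
                             n_target = nrow(pts), observed = res$observed,
                             null_mean = res$null_mean, null_sd = res$null_sd,
                             null_max = res$null_max, p = res$p, note = "",
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  ok <- !is.na(out$p)
  out$adjusted_p <- NA_real_
  out$significant <- NA
  if (any(ok)) {
    hc <- holm_correction(out$p[ok], alpha = config$alpha)
    out$adjusted_p[ok] <- hc$adjusted_p
    out$significant[ok] <- hc$significant
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(out, file.path(config$out_dir, "convergence.json"),
                       digits = NA, dataframe = "rows")
  printed <- out
  printed$null_mean <- sprintf("%.2f", printed$null_mean)
  printed$null_sd <- sprintf("%.2f", printed$null_sd)
  printed$p <- sprintf("%.3f", printed$p)
  printed$adjusted_p <- sprintf("%.3f", printed$adjusted_p)
  write_report_csv(printed, file.path(config$out_dir, "convergence.csv"), config)
  invisible(out)
}

#' Write synthetic fixtures to a directory
#'
#' Emits a spectra CSV, a sensitivity CSV for the toy visual system, a
#' Newick tree, a tip-loci CSV and a species table, all generated from the
#' seed — every file consumable by the public readers.
#'
#' @param config a config list (`seed`, `out_dir` used)
#' @param n_species number of synthetic species
#' @return invisibly, the list of written paths
#' @export
cmd_simulate <- function(config, n_species = 20L) {
  scfg <- synthetic_config(seed = config$seed, n_species = n_species,
                           n_planted = max(4L, n_species %/% 4L),
                           convergence_pull = 0.6)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  vs <- make_toy_visual_system(scfg)
  sp <- make_spectra(scfg)
  ds <- simulate_dataset(scfg)
  paths <- list(
    spectra = file.path(config$out_dir, "spectra.csv"),
    sensitivity = file.path(config$out_dir, "sensitivity.csv"),
    tree = file.path(config$out_dir, "tree.nwk"),
    loci = file.path(config$out_dir, "tip_loci.csv"),
    species = file.path(config$out_dir, "species.csv"))
  flowers <- sp[grep("^sp", names(sp))]
  for (i in seq_along(flowers)) flowers[[i]]$label <- ds$tree$tip.label[i]
  write_spectra(flowers, paths$spectra)
  write_spectra(vs$sensitivities, paths$sensitivity)
  ape::write.tree(ds$tree, paths$tree)
  loci <- data.frame(species = rownames(ds$tips), ds$tips,
                     stringsAsFactors = FALSE)
  write.csv(loci, paths$loci, row.names = FALSE)
  write.csv(data.frame(species = rownames(ds$tips),
                       visitation = ifelse(rownames(ds$tips) %in% ds$planted,
                                           "bird", "insect"),
                       subgroup = ifelse(rownames(ds$tips) %in% ds$planted,
                                         "red_arm", NA_character_),
                       stringsAsFactors = FALSE),
            paths$species, row.names = FALSE)
  invisible(paths)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `loci`, `occupancy`, `convergence` and
#' `simulate`. Flags: `--config <file>` plus per-key overrides
#' (`--tree x.nwk --seed 7 --n_sim 999 ...`). Used by the installed
#' `inst/cli/tetraconv` script.
#'
#' @param args character vector, default `commandArgs(trailingOnly = TRUE)`
#' @return the subcommand's value, invisibly
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) < 1L)
    stop("usage: tetraconv <loci|occupancy|convergence|simulate> [--config f] [--key value ...]")
  cmd <- args[1]
  args <- args[-1]
  config_path <- NULL
  overrides <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop("unexpected argument: ", args[i])
    key <- sub("^--", "", args[i])
    if (i + 1L > length(args)) stop("missing value for --", key)
    val <- args[i + 1L]
    if (key == "config") config_path <- val else overrides[[key]] <- val
    i <- i + 2L
  }
  config <- read_run_config(config_path, overrides)
  message(sprintf("[tetraconv %s] %s seed=%d n_sim=%d", pkg_version(), cmd,
                  config$seed, config$n_sim))
  switch(cmd,
         loci = cmd_loci(config),
         occupancy = cmd_occupancy(config),
         convergence = cmd_convergence(config),
         simulate = cmd_simulate(config),
         stop("unknown subcommand: ", cmd))
}
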