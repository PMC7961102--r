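# Configuration handling and the command-line pipeline: synth | build |
# ablate | analyze | fit, wiring the generator, builder, geometry and
# fitter together with seeded, reproducible outputs.

## Parse "44-52" / "143-148,349-351" / integer vectors into index vectors.
parse_ranges <- function(x) {
  if (is.numeric(x)) return(sort(unique(as.integer(x))))
  if (!is.character(x)) stop_config("residue ranges must be numeric or text")
  out <- integer(0)
  for (part in strsplit(paste(x, collapse = ","), ",")[[1]]) {
    part <- trimws(part)
    if (part == "") next
    m <- regmatches(part, regexec("^(\\d+)\\s*-\\s*(\\d+)$", part))[[1]]
    if (length(m) == 3L) {
      out <- c(out, as.integer(m[2]):as.integer(m[3]))
    } else if (grepl("^\\d+$", part)) {
      out <- c(out, as.integer(part))
    } else {
      stop_config(sprintf("cannot parse residue range '%s'", part))
    }
  }
  sort(unique(out))
}

#' Default pipeline configuration
#'
#' @return Nested list with sections `selections`, `geometry`, `fit`,
#'   `synth` and `io`.
#' @export
default_config <- function() {
  list(
    version = 1L,
    selections = list(
      dloop = "44-52",
      target_cleft = "143-148,349-351",
      sd1 = "1-32,70-137,338-375",
      sd2 = "33-69",
      sd3 = "138-180,270-337",
      sd4 = "181-269"
    ),
    geometry = list(cutoff = 10, twist_method = "screw", last_k = NULL),
    fit = list(weighting = "none"),
    synth = list(
      kind = "bare",
      n_subunits = 18L,
      twist = 167,
      cofilactin_twist = 162,
      rise = 27.5,
      noise_sd = 0,
      n_frames = 1L,
      seed = 1L,
      transition = list(A1 = 167, A2 = 162, n0 = 9, N = 1.1)
    ),
    io = list()
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file, rejects unknown keys, and merges it over
#' [default_config()].
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop_config(sprintf("config not found: %s", path))
  user <- yaml::read_yaml(path)
  known <- names(cfg)
  bad <- setdiff(names(user), known)
  if (length(bad)) {
    stop_config(sprintf("unknown config key: %s", bad[1]))
  }
  for (sec in names(user)) {
    if (sec == "version") { cfg$version <- user$version; next }
    bad <- setdiff(names(user[[sec]]), names(cfg[[sec]]))
    if (length(bad)) {
      stop_config(sprintf("unknown config key: %s.%s", sec, bad[1]))
    }
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  cfg
}

config_selections <- function(cfg) {
  s <- cfg$selections
  residue_selections(
    dloop = parse_ranges(s$dloop),
    target_cleft = parse_ranges(s$target_cleft),
    subdomains = list(sd1 = parse_ranges(s$sd1), sd2 = parse_ranges(s$sd2),
                      sd3 = parse_ranges(s$sd3), sd4 = parse_ranges(s$sd4))
  )
}

.write_csv <- function(df, path) {
  utils::write.csv(format(df, scientific = FALSE, trim = TRUE), path,
                   row.names = FALSE, quote = FALSE)
  path
}

#' Read an angle profile from CSV
#'
#' Expects columns `frame`, `position_n`, `value_deg` (the format written by
#' the `analyze` subcommand).
#'
#' @param path CSV file path.
#' @param observable Label for the profile.
#' @return An [angle_profile()].
#' @export
profile_from_csv <- function(path, observable = "twist") {
  df <- utils::read.csv(path)
  need <- c("frame", "position_n", "value_deg")
  if (!all(need %in% names(df))) {
    stop_input("profile CSV needs columns frame, position_n, value_deg")
  }
  pos <- sort(unique(df$position_n))
  frames <- sort(unique(df$frame))
  vals <- matrix(NA_real_, length(pos), length(frames))
  vals[cbind(match(df$position_n, pos), match(df$frame, frames))] <-
    df$value_deg
  angle_profile(observable, pos, vals)
}

.usage <- function() {
  message(paste(
    "usage: cofilactin-tools <synth|build|ablate|analyze|fit> [options]",
    "  synth    --out DIR [--config FILE] [--seed INT] [--kind bare|cofilactin|boundary]",
    "  build    --bare PDB --cofilactin PDB --mode slow|fast [--out DIR]",
    "  ablate   --input PDB --keep K1,K2,... [--out DIR]",
    "  analyze  --input PDB [--config FILE] [--out DIR]",
    "  fit      --input CSV [--config FILE] [--out DIR]",
    sep = "\n"
  ))
}

.parse_argv <- function(argv) {
  flags <- list()
  positional <- character(0)
  i <- 1L
  valued <- c("--config", "--seed", "--out", "--mode", "--keep", "--bare",
              "--cofilactin", "--map", "--bare-map", "--cofilactin-map",
              "--kind", "--input")
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      if (!a %in% valued || i == length(argv)) return(NULL)
      flags[[substring(a, 3)]] <- argv[i + 1L]
      i <- i + 2L
    } else {
      positional <- c(positional, a)
      i <- i + 1L
    }
  }
  list(flags = flags, positional = positional)
}

.read_map <- function(path) {
  if (is.null(path)) return(NULL)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

.write_log <- function(out_dir, cfg_path, outputs) {
  hash <- if (!is.null(cfg_path)) unname(tools::md5sum(cfg_path)) else "default"
  lines <- c(
    sprintf("cofilactin %s | R %s.%s",
            as.character(utils::packageVersion("cofilactin")),
            R.version$major, R.version$minor),
    sprintf("config: %s", hash),
    sprintf("output: %s", outputs)
  )
  writeLines(lines, file.path(out_dir, "run.log"))
}

#' Run a pipeline subcommand
#'
#' Entry point behind the `cofilactin-tools` launcher script. Subcommands:
#' `synth` writes a synthetic filament PDB (+ chain map CSV); `build`
#' splices a slow/fast boundary from two input PDBs; `ablate` removes
#' cofilins per keep-list; `analyze` emits twist/geometry/contacts/rmsd
#' CSVs; `fit` reads a profile CSV and emits the transition-fit JSON.
#'
#' @param argv Character vector of command-line arguments.
#' @return Exit status, invisibly: 0 success, 1 domain error, 2 usage error.
#' @export
run_command <- function(argv) {
  cmds <- c("synth", "build", "ablate", "analyze", "fit")
  if (length(argv) == 0L || !argv[1] %in% cmds) {
    .usage()
    return(invisible(2L))
  }
  parsed <- .parse_argv(argv[-1])
  if (is.null(parsed)) {
    .usage()
    return(invisible(2L))
  }
  fl <- parsed$flags
  status <- tryCatch({
    cfg <- load_config(fl$config)
    out_dir <- fl$out %||% "."
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    outputs <- switch(argv[1],
      synth = .cmd_synth(fl, cfg, out_dir),
      build = .cmd_build(fl, cfg, out_dir),
      ablate = .cmd_ablate(fl, cfg, out_dir),
      analyze = .cmd_analyze(fl, cfg, out_dir),
      fit = .cmd_fit(fl, cfg, out_dir)
    )
    .write_log(out_dir, fl$config, outputs)
    0L
  }, cofilactin_error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

.cmd_synth <- function(fl, cfg, out_dir) {
  sy <- cfg$synth
  seed <- as.integer(fl$seed %||% sy$seed)
  kind <- fl$kind %||% sy$kind
  sel <- config_selections(cfg)
  noise <- noise_model(sy$noise_sd, sy$n_frames, seed)
  n <- as.integer(sy$n_subunits)
  sys <- switch(kind,
    bare = make_filament(
      make_subunit_template(-9, 25, seed = seed, dloop = "extended",
                            conformation_label = "bare", selections = sel),
      n_subunits = n, helical = helical_params(sy$twist, sy$rise),
      noise = noise),
    cofilactin = make_filament(
      make_subunit_template(-28.9, 24, seed = seed, dloop = "retracted",
                            conformation_label = "cofilactin",
                            selections = sel),
      n_subunits = n,
      helical = helical_params(sy$cofilactin_twist, sy$rise),
      occupancy = seq_len(n - 2L), noise = noise),
    boundary = {
      tp <- sy$transition
      params <- transition_params(tp$A1, tp$A2, tp$n0, tp$N)
      make_filament(
        make_subunit_template(-9, 25, seed = seed, dloop = "extended",
                              conformation_label = "bare",
                              selections = sel),
        n_subunits = n,
        helical = helical_params(evaluate_transition(params,
                                                     seq_len(n - 1L)),
                                 sy$rise),
        noise = noise)
    },
    stop_config(sprintf("unknown synth kind '%s'", kind))
  )
  pdb <- file.path(out_dir, "filament.pdb")
  cmap <- write_system(sys, pdb)
  chains <- .write_csv(cmap, file.path(out_dir, "chains.csv"))
  c(pdb, chains)
}

.cmd_build <- function(fl, cfg, out_dir) {
  if (is.null(fl$bare) || is.null(fl$cofilactin) || is.null(fl$mode)) {
    stop_config("build requires --bare, --cofilactin and --mode")
  }
  sel <- config_selections(cfg)
  bare <- read_system(fl$bare, chain_map = .read_map(fl[["bare-map"]]),
                      selections = sel)
  cof <- read_system(fl$cofilactin,
                     chain_map = .read_map(fl[["cofilactin-map"]]),
                     selections = sel)
  sys <- splice_boundary(bare, cof, mode = fl$mode)
  pdb <- file.path(out_dir, "boundary.pdb")
  cmap <- write_system(sys, pdb)
  chains <- .write_csv(cmap, file.path(out_dir, "chains.csv"))
  bjson <- file.path(out_dir, "boundary.json")
  sp <- sys$boundary
  jsonlite::write_json(
    list(mode = sp$mode, bare_count = sp$bare_count,
         cofilactin_count = sp$cofilactin_count,
         cofilin_count = sp$cofilin_count,
         interfacial_index = sp$interfacial_index,
         requires_relaxation = sp$requires_relaxation,
         putative_severing_pairs = putative_severing_interface(sp)),
    bjson, auto_unbox = TRUE, digits = NA
  )
  c(pdb, chains, bjson)
}

.cmd_ablate <- function(fl, cfg, out_dir) {
  if (is.null(fl$input)) stop_config("ablate requires --input")
  sel <- config_selections(cfg)
  sys <- read_system(fl$input, chain_map = .read_map(fl$map),
                     selections = sel)
  keep <- if (is.null(fl$keep) || fl$keep == "") integer(0) else
    as.integer(strsplit(fl$keep, ",")[[1]])
  sys <- ablate_cofilins(sys, keep)
  pdb <- file.path(out_dir, "ablated.pdb")
  cmap <- write_system(sys, pdb)
  chains <- .write_csv(cmap, file.path(out_dir, "chains.csv"))
  c(pdb, chains)
}

.cmd_analyze <- function(fl, cfg, out_dir) {
  if (is.null(fl$input)) stop_config("analyze requires --input")
  sel <- config_selections(cfg)
  sys <- read_system(fl$input, chain_map = .read_map(fl$map),
                     selections = sel)
  geo <- cfg$geometry
  outputs <- character(0)

  tw <- twist_profile(sys, method = geo$twist_method)
  outputs <- c(outputs, .write_csv(as.data.frame(tw),
                                   file.path(out_dir, "twist.csv")))
  st <- per_position_stats(tw, geo$last_k %||% NULL)
  outputs <- c(outputs, .write_csv(st, file.path(out_dir,
                                                 "twist_summary.csv")))
  outputs <- c(outputs, .write_csv(geometry_records(sys),
                                   file.path(out_dir, "geometry.csv")))
  if (n_subunits(sys) >= 3L) {
    cp <- dloop_contact_profile(sys, spec = contact_spec(cutoff = geo$cutoff))
    outputs <- c(outputs, .write_csv(as.data.frame(cp),
                                     file.path(out_dir, "contacts.csv")))
    outputs <- c(outputs, .write_csv(interface_integrity(sys,
                                                         cutoff = geo$cutoff),
                                     file.path(out_dir, "interfaces.csv")))
  }
  rs <- rmsd_series(sys, positions(sys), reference = 1L)
  outputs <- c(outputs, .write_csv(as.data.frame(rs),
                                   file.path(out_dir, "rmsd.csv")))
  outputs
}

.cmd_fit <- function(fl, cfg, out_dir) {
  if (is.null(fl$input)) stop_config("fit requires --input")
  profile <- profile_from_csv(fl$input)
  fit <- fit_transition(profile, weighting = cfg$fit$weighting)
  out <- file.path(out_dir, "fit.json")
  write_transition_fit(fit, out)
  out
}
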