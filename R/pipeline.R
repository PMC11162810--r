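#' End-to-end knockout-panel benchmark
#'
#' Simulates the full MALDI mapping study on synthetic data: tRNAs with
#' known per-site enzyme efficiencies (two sites each, 17 and 20), one
#' simulated peak list per strain per tRNA (each peak list represents
#' the digest of one purified tRNA species, as on a MALDI plate), and
#' attribution through the analytical grid. Returns the per-site truth
#' and recovered attribution.
#'
#' @param n_trnas Number of synthetic tRNAs (two candidate sites each).
#' @param seed Integer seed controlling every random draw.
#' @param noise A [noise_config()]; use [zero_noise()] for the exact
#'   check.
#' @param enzyme Digestion enzyme.
#' @return data.frame with columns `trna_id`, `site`, `truth`,
#'   `attribution`, `correct`.
#' @export
simulate_knockout_benchmark <- function(n_trnas = 100, seed = 1L,
                                        noise = noise_config(),
                                        enzyme = "RNaseT1") {
  scen <- gen_site_scenarios(2L * n_trnas, seed)
  strains <- c("WT", "dB1", "dB2", "dB1dB2")
  out <- list()
  for (k in seq_len(n_trnas)) {
    s17 <- scen[2L * k - 1L, ]
    s20 <- scen[2L * k, ]
    profile <- list("17" = c(B1 = s17$eff_B1, B2 = s17$eff_B2),
                    "20" = c(B1 = s20$eff_B1, B2 = s20$eff_B2))
    gen <- gen_trna_set(1L, seed + k, profile)
    trna <- gen$trnas[[1L]]
    peaks <- lapply(seq_along(strains), function(g) {
      gen_maldi_panel(gen$trnas, gen$map, strains[g], noise,
                      seed = seed + 1000L + 4L * k + g, enzyme = enzyme)
    })
    names(peaks) <- strains
    panel <- attribute_panel(trna, peaks, enzyme = enzyme)
    truth <- c("17" = s17$truth, "20" = s20$truth)
    panel$truth <- truth[panel$site]
    out[[k]] <- data.frame(trna_id = panel$trna_id, site = panel$site,
                           truth = panel$truth,
                           attribution = panel$attribution,
                           correct = panel$attribution == panel$truth,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Attribution accuracy of a benchmark result
#'
#' @param benchmark Output of [simulate_knockout_benchmark()].
#' @return Fraction of sites whose attribution equals the ground truth.
#' @export
attribution_accuracy <- function(benchmark) {
  mean(benchmark$correct)
}

#' Join MALDI and sequencing attributions per site
#'
#' @param maldi,seq data.frames with columns `trna_id`, `site`,
#'   `attribution`; either may be NULL (columns reported
#'   `not_available`).
#' @return data.frame with both attributions and an `agree` flag
#'   (`NA` where one method is unavailable).
#' @export
join_attributions <- function(maldi = NULL, seq = NULL) {
  grab <- function(d, col) {
    if (is.null(d)) return(NULL)
    data.frame(trna_id = d$trna_id, site = d$site, x = d$attribution,
               stringsAsFactors = FALSE, check.names = FALSE) |>
      stats::setNames(c("trna_id", "site", col))
  }
  m <- grab(maldi, "maldi_attribution")
  s <- grab(seq, "seq_attribution")
  out <- if (is.null(m)) s else if (is.null(s)) m else
    merge(m, s, by = c("trna_id", "site"), all = TRUE)
  if (is.null(out)) stop("at least one of maldi/seq must be supplied")
  if (is.null(out$maldi_attribution)) out$maldi_attribution <- NA_character_
  if (is.null(out$seq_attribution)) out$seq_attribution <- NA_character_
  out$maldi_attribution[is.na(out$maldi_attribution)] <- "not_available"
  out$seq_attribution[is.na(out$seq_attribution)] <- "not_available"
  both <- out$maldi_attribution != "not_available" &
    out$seq_attribution != "not_available"
  out$agree <- ifelse(both, out$maldi_attribution == out$seq_attribution, NA)
  out[order(out$trna_id, position_label_key(out$site)), , drop = FALSE]
}

#' Simulate and write a complete synthetic study to disk
#'
#' Writes everything the analysis commands consume: tRNA FASTA +
#' modification TSV, one peak-list TSV per strain and tRNA, one cleavage
#' count table per strain and replicate, and a manifest JSON recording
#' all parameters and seeds. Byte-identical across runs with the same
#' arguments.
#'
#' @param out_dir Output directory (created if needed).
#' @param n_trnas Number of synthetic tRNAs.
#' @param seed Integer seed.
#' @param noise A [noise_config()].
#' @param replicates Cleavage-profile replicates per strain.
#' @param enzyme Digestion enzyme.
#' @return Invisibly, the manifest list.
#' @export
simulate_study <- function(out_dir, n_trnas = 3, seed = 1L,
                           noise = noise_config(), replicates = 3L,
                           enzyme = "RNaseT1") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scen <- gen_site_scenarios(2L * n_trnas, seed)
  strains <- c("WT", "dB1", "dB2", "dB1dB2")
  trnas <- list()
  maps <- list()
  for (k in seq_len(n_trnas)) {
    s17 <- scen[2L * k - 1L, ]
    s20 <- scen[2L * k, ]
    profile <- list("17" = c(B1 = s17$eff_B1, B2 = s17$eff_B2),
                    "20" = c(B1 = s20$eff_B1, B2 = s20$eff_B2))
    gen <- gen_trna_set(1L, seed + k, profile,
                        id_prefix = sprintf("synth_t%03d_", k))
    trnas <- c(trnas, gen$trnas)
    maps[[k]] <- gen$map
  }
  map <- do.call(rbind, maps)
  write_trna_set(trnas, file.path(out_dir, "trnas.fasta"),
                 file.path(out_dir, "modifications.tsv"),
                 file.path(out_dir, "labels.tsv"))
  utils::write.table(map, file.path(out_dir, "truth_map.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (g in seq_along(strains)) {
    for (k in seq_len(n_trnas)) {
      id <- names(trnas)[k]
      peaks <- gen_maldi_panel(trnas[k], map, strains[g], noise,
                               seed = seed + 1000L + 4L * k + g,
                               enzyme = enzyme)
      utils::write.table(peaks,
                         file.path(out_dir, paste0("peaks_", id, "_",
                                                   strains[g], ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    profiles <- gen_cleavage_profiles(trnas, map, strains[g],
                                      replicates = replicates, noise = noise,
                                      seed = seed + 5000L + g)
    for (r in seq_len(replicates)) {
      sel <- Filter(function(p) p$replicate == r, profiles)
      write_cleavage_table(sel,
                           file.path(out_dir, paste0("cleavage_", strains[g],
                                                     "_rep", r, ".tsv")))
    }
  }
  manifest <- list(n_trnas = n_trnas, seed = seed, replicates = replicates,
                   enzyme = enzyme, strains = strains,
                   noise = unclass(noise),
                   sites_per_trna = c("17", "20"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

# ---- command-line interface -------------------------------------------

cli_parse <- function(args) {
  flags <- list()
  positional <- character()
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i == length(args) || startsWith(args[[i + 1L]], "--")) {
        flags[[key]] <- TRUE
        i <- i + 1L
      } else {
        flags[[key]] <- args[[i + 1L]]
        i <- i + 2L
      }
    } else {
      positional <- c(positional, a)
      i <- i + 1L
    }
  }
  list(flags = flags, positional = positional)
}

cli_flag <- function(parsed, name, default = NULL, required = FALSE) {
  v <- parsed$flags[[name]]
  if (is.null(v)) {
    if (required) stop("missing required flag --", name)
    return(default)
  }
  v
}

cli_log <- function(...) message("[dusmapr] ", ...)

#' Command-line entry point
#'
#' Thin dispatcher over the package's analysis functions; the installed
#' script `inst/cli/dusmapr` forwards `commandArgs(TRUE)` here. Verbs:
#' `digest`, `mass`, `diagnose`, `attribute`, `alkascore`, `kinetics`,
#' `simulate`, `report`. Run `dus_cli("help")` for flag summaries. All
#' outputs are TSV/JSON and reproducible from flags plus `--seed`.
#'
#' @param args Character vector of command-line arguments, the first
#'   being the verb.
#' @return Invisibly, the verb's result table; called for its file
#'   side effects.
#' @export
dus_cli <- function(args) {
  if (!length(args) || args[[1L]] %in% c("help", "--help", "-h")) {
    cat("usage: dusmapr <verb> [--flags]\n",
        "verbs:\n",
        "  digest    --fasta F --mods M [--enzyme RNaseT1] [--missed 0] --out TSV\n",
        "  mass      --fragments UDG,UUG,... --out TSV\n",
        "  diagnose  --fasta F --mods M [--enzyme E] [--tolerance-da 0.5] --out TSV\n",
        "  attribute --fasta F --mods M --peaks-wt P --peaks-db1 P --peaks-db2 P\n",
        "            --peaks-double P [--enzyme E] [--tolerance-da 0.5] --out TSV\n",
        "            [--json J]\n",
        "  alkascore --counts TSV --fasta F [--threshold 5] [--window 10] --out TSV\n",
        "  kinetics  --table TSV --enzyme-conc E --out JSON\n",
        "  simulate  --out-dir D [--n 3] [--seed 1] [--replicates 3]\n",
        "  report    [--maldi TSV] [--seq TSV] --out TSV\n", sep = "")
    return(invisible(NULL))
  }
  verb <- args[[1L]]
  p <- cli_parse(args[-1L])
  result <- switch(verb,
    digest = cli_digest(p),
    mass = cli_mass(p),
    diagnose = cli_diagnose(p),
    attribute = cli_attribute(p),
    alkascore = cli_alkascore(p),
    kinetics = cli_kinetics(p),
    simulate = cli_simulate(p),
    report = cli_report(p),
    stop("unknown verb: ", verb))
  invisible(result)
}

cli_read_trnas <- function(p) {
  read_trna_set(cli_flag(p, "fasta", required = TRUE),
                cli_flag(p, "mods"),
                cli_flag(p, "labels"))
}

cli_digest <- function(p) {
  trnas <- cli_read_trnas(p)
  enzyme <- cli_flag(p, "enzyme", "RNaseT1")
  missed <- as.integer(cli_flag(p, "missed", 0L))
  frags <- unlist(lapply(trnas, digest, enzyme = enzyme,
                         missed_cleavages = missed), recursive = FALSE)
  out <- cli_flag(p, "out", required = TRUE)
  tab <- write_fragment_table(frags, out)
  cli_log("wrote ", nrow(tab), " fragments to ", out)
  tab
}

cli_mass <- function(p) {
  strings <- strsplit(cli_flag(p, "fragments", required = TRUE), ",")[[1L]]
  frags <- lapply(strings, fragment_from_string)
  out <- cli_flag(p, "out", required = TRUE)
  tab <- write_peak_table(frags, out)
  cli_log("wrote ", nrow(tab), " theoretical peaks to ", out)
  tab
}

cli_diagnose <- function(p) {
  trnas <- cli_read_trnas(p)
  enzyme <- cli_flag(p, "enzyme", "RNaseT1")
  tol <- as.numeric(cli_flag(p, "tolerance-da", 0.5))
  tabs <- lapply(trnas, select_diagnostics, enzyme = enzyme,
                 tolerance_da = tol)
  tab <- do.call(rbind, tabs)
  out <- cli_flag(p, "out", required = TRUE)
  utils::write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  cli_log("wrote ", nrow(tab), " diagnostics to ", out)
  tab
}

cli_attribute <- function(p) {
  trnas <- cli_read_trnas(p)
  enzyme <- cli_flag(p, "enzyme", "RNaseT1")
  tol <- as.numeric(cli_flag(p, "tolerance-da", 0.5))
  peaks <- list(WT = read_peak_list(cli_flag(p, "peaks-wt", required = TRUE)),
                dB1 = read_peak_list(cli_flag(p, "peaks-db1", required = TRUE)),
                dB2 = read_peak_list(cli_flag(p, "peaks-db2", required = TRUE)),
                dB1dB2 = read_peak_list(cli_flag(p, "peaks-double",
                                                 required = TRUE)))
  tab <- do.call(rbind, lapply(trnas, attribute_panel, peak_lists = peaks,
                               enzyme = enzyme, tolerance_da = tol))
  write_panel_report(tab, cli_flag(p, "out", required = TRUE),
                     cli_flag(p, "json"))
  cli_log("attributed ", nrow(tab), " site(s)")
  tab
}

cli_alkascore <- function(p) {
  profiles <- read_cleavage_table(cli_flag(p, "counts", required = TRUE))
  trnas <- cli_read_trnas(p)
  threshold <- as.numeric(cli_flag(p, "threshold", 5))
  window <- as.integer(cli_flag(p, "window", 10L))
  tabs <- lapply(names(profiles), function(id) {
    if (!id %in% names(trnas)) stop("no tRNA sequence for profile ", id)
    calls <- call_sites(profiles[[id]], trnas[[id]],
                        score_threshold = threshold, window = window)
    if (nrow(calls)) cbind(trna_id = id, calls) else NULL
  })
  tab <- do.call(rbind, tabs)
  out <- cli_flag(p, "out", required = TRUE)
  if (is.null(tab)) {
    tab <- data.frame(trna_id = character(), position = integer(),
                      base = character(), normcount = numeric(),
                      stop_ratio = numeric(), channel = character(),
                      substoichiometric = logical())
  }
  utils::write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  cli_log("wrote ", nrow(tab), " called site(s) to ", out)
  tab
}

cli_kinetics <- function(p) {
  series <- read_kinetics_table(cli_flag(p, "table", required = TRUE),
                                as.numeric(cli_flag(p, "enzyme-conc",
                                                    required = TRUE)))
  fits <- lapply(series, fit_michaelis_menten)
  out <- cli_flag(p, "out", required = TRUE)
  write_kinetics_report(fits, out)
  cli_log("fitted ", length(fits), " substrate series")
  fits
}

cli_simulate <- function(p) {
  simulate_study(cli_flag(p, "out-dir", required = TRUE),
                 n_trnas = as.integer(cli_flag(p, "n", 3L)),
                 seed = as.integer(cli_flag(p, "seed", 1L)),
                 replicates = as.integer(cli_flag(p, "replicates", 3L)))
}

cli_report <- function(p) {
  read_or_null <- function(path) {
    if (is.null(path)) NULL else utils::read.delim(path,
                                                   stringsAsFactors = FALSE)
  }
  maldi <- read_or_null(cli_flag(p, "maldi"))
  seq <- read_or_null(cli_flag(p, "seq"))
  tab <- join_attributions(maldi, seq)
  out <- cli_flag(p, "out", required = TRUE)
  utils::write.table(tab, out, sep = "\t", quote = FALSE, row.names = FALSE)
  n_dis <- sum(!is.na(tab$agree) & !tab$agree)
  cli_log("joined ", nrow(tab), " site(s); ", n_dis, " disagreement(s)")
  tab
}
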