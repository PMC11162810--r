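#' Noise configuration for the synthetic generators
#'
#' @param mz_jitter_sd Gaussian m/z jitter of simulated MALDI peaks
#'   (Da).
#' @param intensity_cv Coefficient of variation of the log-normal
#'   multiplicative intensity noise.
#' @param background_lambda Mean Poisson background of cleavage
#'   read-start counts per position.
#' @param coverage Traversing reads per position in cleavage profiles.
#' @return A `noise_config` list.
#' @export
noise_config <- function(mz_jitter_sd = 0.05, intensity_cv = 0.2,
                         background_lambda = 5, coverage = 1000) {
  stopifnot(mz_jitter_sd >= 0, intensity_cv >= 0, background_lambda >= 0,
            coverage > 0)
  structure(list(mz_jitter_sd = mz_jitter_sd, intensity_cv = intensity_cv,
                 background_lambda = background_lambda, coverage = coverage),
            class = "noise_config")
}

#' Zero-noise configuration
#' @export
zero_noise <- function() noise_config(0, 0, 0, 1000)

# mean-1 log-normal multiplier with the requested cv
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# D-site sequence contexts implanted into synthetic tRNAs. Each entry
# gives the canonical numbers it occupies, the bases written there, which
# one is the site, and any insertion labels. Contexts reproduce the
# diagnostic digestion fragments observed for B. subtilis tRNAs
# (UDG for 17, DAG for 20, CDAG for 20a, DCG for 47) so each site yields
# a small RNase T1 product containing exactly one candidate uridine.
.site_contexts <- list(
  "16"  = list(numbers = 13:17, bases = c("G", "C", "C", "U", "G"),
               site_number = 16, insertions = NULL),
  "17"  = list(numbers = 15:18, bases = c("G", "U", "U", "G"),
               site_number = 17, insertions = NULL),
  "20"  = list(numbers = 19:22, bases = c("G", "U", "A", "G"),
               site_number = 20, insertions = NULL),
  "20a" = list(numbers = 19:22, bases = c("G", "C", NA, "A", "G"),
               site_number = NA, insertions = list(after = 20, labels = "20a",
                                                  bases = "U")),
  "20b" = list(numbers = 19:21, bases = c("G", "A", NA, NA, "G"),
               site_number = NA, insertions = list(after = 20,
                                                  labels = c("20a", "20b"),
                                                  bases = c("A", "U"))),
  "47"  = list(numbers = 46:49, bases = c("G", "U", "C", "G"),
               site_number = 47, insertions = NULL)
)

#' Generate synthetic annotated tRNAs with a known specificity map
#'
#' Builds cloverleaf-length (76 nt plus insertions) synthetic sequences
#' with designated dihydrouridine sites embedded in the local contexts
#' that make them monitorable by RNase T1 MALDI diagnostics (UDG at 17,
#' DAG at 20, CDAG at 20a, DCG at 47). Filler positions are drawn from
#' A/G only, so filler digestion fragments can never collide in mass
#' with the pyrimidine-containing diagnostic pairs. The attached ground
#' truth records, per site, the efficiency of each synthase; the
#' wild-type stoichiometry of a site served by several enzymes is
#' `1 - prod(1 - eff)`.
#'
#' At most one of the D-loop insertion region sites (20, 20a, 20b) and
#' one of (16, 17) can be designed into the same molecule; their
#' contexts overlap.
#'
#' @param n Number of tRNAs.
#' @param seed Integer seed.
#' @param site_profile Named list: site label -> named numeric vector of
#'   enzyme efficiencies in [0, 1], e.g.
#'   `list("17" = c(B1 = 0.9), "20" = c(B1 = 0.9, B2 = 0.9))`. Applied
#'   to every generated tRNA.
#' @param id_prefix Prefix for generated tRNA ids.
#' @return List with `trnas` (named list of [annotated_trna()]) and
#'   `map` (data.frame: `trna_id`, `site`, `eff_B1`, `eff_B2`,
#'   `wt_stoich`).
#' @export
gen_trna_set <- function(n, seed,
                         site_profile = list("17" = c(B1 = 0.9),
                                             "20" = c(B1 = 0.9, B2 = 0.9)),
                         id_prefix = "synth_t") {
  stopifnot(n >= 1)
  set.seed(seed)
  sites <- names(site_profile)
  unknown <- setdiff(sites, names(.site_contexts))
  if (length(unknown)) {
    stop("no designed context for site(s): ", paste(unknown, collapse = ", "))
  }
  dloop <- intersect(sites, c("20", "20a", "20b"))
  if (length(dloop) > 1L) {
    stop("sites ", paste(dloop, collapse = ", "),
         " share the D-loop insertion context; design one per tRNA")
  }
  if (all(c("16", "17") %in% sites)) {
    stop("sites 16 and 17 share a context; design one per tRNA")
  }

  trnas <- vector("list", n)
  map_rows <- list()
  for (k in seq_len(n)) {
    id <- sprintf("%s%03d", id_prefix, k)
    bases <- sample(c("A", "G"), 76, replace = TRUE, prob = c(0.65, 0.35))
    numbers <- 1:76
    labels <- as.character(numbers)
    # implant fixed contexts on canonical numbers
    for (site in sites) {
      ctx <- .site_contexts[[site]]
      keep <- !is.na(ctx$bases)
      bases[match(ctx$numbers, numbers)] <- ctx$bases[keep]
    }
    # insertions (20a/20b) extend the molecule
    for (site in sites) {
      ins <- .site_contexts[[site]]$insertions
      if (is.null(ins)) next
      at <- match(as.character(ins$after), labels)
      bases <- append(bases, ins$bases, after = at)
      labels <- append(labels, ins$labels, after = at)
    }
    mods <- data.frame(position_label = sites,
                       modification_code = "D", stringsAsFactors = FALSE)
    trnas[[k]] <- annotated_trna(id, paste(bases, collapse = ""),
                                 labels = labels, modifications = mods)
    for (site in sites) {
      eff <- site_profile[[site]]
      e1 <- if ("B1" %in% names(eff)) unname(eff[["B1"]]) else 0
      e2 <- if ("B2" %in% names(eff)) unname(eff[["B2"]]) else 0
      map_rows[[length(map_rows) + 1L]] <- data.frame(
        trna_id = id, site = site, eff_B1 = e1, eff_B2 = e2,
        wt_stoich = 1 - (1 - e1) * (1 - e2), stringsAsFactors = FALSE)
    }
  }
  names(trnas) <- vapply(trnas, `[[`, character(1), "id")
  list(trnas = trnas, map = do.call(rbind, map_rows))
}

# site stoichiometry under a genotype: deleted enzymes contribute nothing
genotype_stoich <- function(eff_B1, eff_B2, genotype) {
  e1 <- if (genotype %in% c("dB1", "dB1dB2")) 0 else eff_B1
  e2 <- if (genotype %in% c("dB2", "dB1dB2")) 0 else eff_B2
  1 - (1 - e1) * (1 - e2)
}

#' Simulate a MALDI peak list for one strain
#'
#' Digests every tRNA and emits one peak per fragment; fragments
#' containing mapped D sites emit a modified/unmodified pair whose
#' intensities split the fragment's total abundance by the
#' genotype-dependent stoichiometry (enzymes deleted in the genotype
#' contribute nothing). Peaks get Gaussian m/z jitter and log-normal
#' intensity noise; zero-intensity members are dropped.
#'
#' @param trnas Named list of [annotated_trna()] (D-annotated, i.e. the
#'   wild-type molecules).
#' @param map Specificity map from [gen_trna_set()].
#' @param genotype One of `"WT"`, `"dB1"`, `"dB2"`, `"dB1dB2"`.
#' @param noise A [noise_config()].
#' @param seed Integer seed.
#' @param enzyme Digestion enzyme.
#' @param base_intensity Mean total intensity per fragment.
#' @return data.frame with columns `mz`, `intensity` (a peak list).
#' @export
gen_maldi_panel <- function(trnas, map, genotype = c("WT", "dB1", "dB2",
                                                     "dB1dB2"),
                            noise = noise_config(), seed = 1L,
                            enzyme = "RNaseT1", base_intensity = 100) {
  genotype <- match.arg(genotype)
  set.seed(seed)
  spec <- mass_spec()
  mz <- numeric()
  intensity <- numeric()
  for (trna in trnas) {
    m <- map[map$trna_id == trna$id, , drop = FALSE]
    site_keys <- position_label_key(m$site)
    frags <- digest(trna, enzyme)
    for (f in frags) {
      span <- c(position_label_key(f$start_label),
                position_label_key(f$end_label))
      inside <- which(site_keys >= span[1] & site_keys <= span[2])
      total <- base_intensity * lognormal_noise(1, noise$intensity_cv)
      if (!length(inside)) {
        mz <- c(mz, fragment_mass(f, spec))
        intensity <- c(intensity, total)
        next
      }
      # joint stoichiometry across contained sites (independent enzymes)
      s <- prod(vapply(inside, function(i) {
        genotype_stoich(m$eff_B1[i], m$eff_B2[i], genotype)
      }, numeric(1)))
      f_mod <- f
      f_unmod <- f
      for (i in inside) {
        j <- which(f$residues$label == m$site[i])
        f_mod$residues$modification[j] <- "D"
        f_unmod$residues$modification[j] <- NA_character_
      }
      mz <- c(mz, fragment_mass(f_mod, spec), fragment_mass(f_unmod, spec))
      intensity <- c(intensity, total * s, total * (1 - s))
    }
  }
  keep <- intensity > 0
  mz <- mz[keep] + stats::rnorm(sum(keep), 0, noise$mz_jitter_sd)
  data.frame(mz = mz, intensity = intensity[keep])
}

#' Simulate cleavage profiles for one strain
#'
#' Per position, background read starts are Poisson with mean
#' `background_lambda`; at each mapped site the cleavage events add a
#' Binomial(coverage, stoichiometry) draw placed at read-start position
#' `site + 1` (aniline cleavage phosphorylates the residue 3' of the
#' lesion, so the generator builds the N+1 offset in and scoring must
#' undo it).
#'
#' @inheritParams gen_maldi_panel
#' @param replicates Number of replicate profiles per tRNA.
#' @param stoich_override Optional function(site_row, genotype) returning
#'   the stoichiometry, replacing the knockout model (used for enzyme
#'   titrations).
#' @return List of [cleavage_profile()]s (tRNAs x replicates).
#' @export
gen_cleavage_profiles <- function(trnas, map, genotype = c("WT", "dB1", "dB2",
                                                           "dB1dB2"),
                                  replicates = 1L, noise = noise_config(),
                                  seed = 1L, stoich_override = NULL) {
  genotype <- match.arg(genotype)
  set.seed(seed)
  out <- list()
  for (trna in trnas) {
    m <- map[map$trna_id == trna$id, , drop = FALSE]
    n <- nrow(trna$residues)
    for (r in seq_len(replicates)) {
      counts <- stats::rpois(n, noise$background_lambda)
      for (i in seq_len(nrow(m))) {
        s <- if (is.null(stoich_override)) {
          genotype_stoich(m$eff_B1[i], m$eff_B2[i], genotype)
        } else {
          stoich_override(m[i, , drop = FALSE], genotype)
        }
        pos <- label_to_index(trna, m$site[i])
        if (pos < n) {
          counts[pos + 1L] <- counts[pos + 1L] +
            stats::rbinom(1L, noise$coverage, s)
        }
      }
      counts <- pmin(counts, noise$coverage)
      out[[length(out) + 1L]] <- cleavage_profile(
        trna$id, counts, noise$coverage, sample = genotype, replicate = r)
    }
  }
  out
}

#' Simulate a Michaelis-Menten rate series
#'
#' `v = kcat * E * S / (KM + S)` with multiplicative Gaussian noise of
#' coefficient of variation `cv`. The default concentration grid spans
#' 0.25x to 8x KM with 8 points, covering both sides of the Michaelis
#' constant.
#'
#' @param kcat Turnover number (s^-1).
#' @param KM Michaelis constant (uM).
#' @param enzyme_conc Enzyme concentration (uM).
#' @param conc_grid Substrate concentrations (uM); default
#'   `KM * c(0.25, 0.5, 1, 2, 3, 4, 6, 8)`.
#' @param cv Multiplicative noise CV (0 for the exact curve).
#' @param seed Integer seed.
#' @param substrate_name Substrate label.
#' @return A [rate_series()].
#' @export
gen_kinetics <- function(kcat, KM, enzyme_conc = 1, conc_grid = NULL,
                         cv = 0.02, seed = 1L, substrate_name = "NADPH") {
  if (is.null(conc_grid)) conc_grid <- KM * c(0.25, 0.5, 1, 2, 3, 4, 6, 8)
  if (min(conc_grid) > KM || max(conc_grid) < KM) {
    stop("concentration grid must span KM")
  }
  set.seed(seed)
  v <- kcat * enzyme_conc * conc_grid / (KM + conc_grid)
  if (cv > 0) v <- v * (1 + stats::rnorm(length(v), 0, cv))
  rate_series(conc_grid, v, enzyme_conc, substrate_name)
}

#' Simulate a cooperative binding titration
#'
#' Hill isotherm `dF = A * S^n / (K_half^n + S^n)` with multiplicative
#' Gaussian noise.
#'
#' @param K_half Half-transition concentration (uM).
#' @param hill_n Hill coefficient.
#' @param amplitude Saturating fluorescence change.
#' @param conc_grid Titrant concentrations (uM).
#' @param cv Multiplicative noise CV.
#' @param seed Integer seed.
#' @return data.frame with columns `conc`, `delta_f`.
#' @export
gen_binding_titration <- function(K_half, hill_n = 2, amplitude = 1,
                                  conc_grid = NULL, cv = 0, seed = 1L) {
  if (is.null(conc_grid)) {
    conc_grid <- K_half * c(0.1, 0.25, 0.5, 0.75, 1, 1.5, 2, 3, 5, 8)
  }
  set.seed(seed)
  dF <- amplitude * conc_grid^hill_n / (K_half^hill_n + conc_grid^hill_n)
  if (cv > 0) dF <- dF * (1 + stats::rnorm(length(dF), 0, cv))
  data.frame(conc = conc_grid, delta_f = dF)
}

#' Sample decodable enzyme-specificity scenarios
#'
#' Draws per-site ground-truth attribution classes with efficiency
#' ranges chosen so the knockout-panel grid can in principle decode
#' them: dedicated enzymes install near-stoichiometrically (0.90-0.98,
#' the MALDI regime where the diagnostic peak is present at control
#' intensity or absent), the weaker partner of a preferred pair at
#' 0.3-0.5, absent enzymes at 0.
#'
#' @param n Number of sites.
#' @param seed Integer seed.
#' @param classes Scenario classes to draw from.
#' @return data.frame with columns `truth`, `eff_B1`, `eff_B2`.
#' @export
gen_site_scenarios <- function(n, seed,
                               classes = c("B1_only", "B2_only", "redundant",
                                           "redundant_B1_preferred",
                                           "redundant_B2_preferred")) {
  set.seed(seed)
  truth <- sample(classes, n, replace = TRUE)
  hi <- function(k) stats::runif(k, 0.90, 0.98)
  lo <- function(k) stats::runif(k, 0.3, 0.5)
  e1 <- numeric(n)
  e2 <- numeric(n)
  for (cls in classes) {
    i <- which(truth == cls)
    k <- length(i)
    if (!k) next
    switch(cls,
      B1_only = { e1[i] <- hi(k); e2[i] <- 0 },
      B2_only = { e1[i] <- 0; e2[i] <- hi(k) },
      redundant = { e1[i] <- hi(k); e2[i] <- hi(k) },
      # preference: the preferred enzyme carries the high efficiency, so
      # deleting it leaves only the weak partner's signal
      redundant_B1_preferred = { e1[i] <- hi(k); e2[i] <- lo(k) },
      redundant_B2_preferred = { e1[i] <- lo(k); e2[i] <- hi(k) })
  }
  data.frame(truth = truth, eff_B1 = e1, eff_B2 = e2,
             stringsAsFactors = FALSE)
}
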