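# Synthetic multi-dataset metabarcoding corpus with known ground truth.
#
# The generator emulates the statistical structure of an integrated
# 18S-V4 metabarcoding study: six datasets (three fortnightly multi-year
# time series, two oceanographic campaigns, one coastal survey) spread
# over six sea regions, exact-identity sequence redundancy within planted
# groups (copies and >= 80%-coverage substrings of a group master
# sequence), dispersed-mutation decoys, partially unassigned taxonomy and
# planted periodic abundance series. Guarantees are constructive: in-group
# pairs always satisfy the edge rule (members are nested prefixes of the
# master) and cross-group pairs never do (master pairs are checked against
# the longest-common-substring bound at generation time and redrawn if
# needed), so partition-recovery tests are exact.

.SITES <- data.frame(
  dataset = c("ASTAN", "BBMO", "SOLA"),
  region = c("English Channel", "Mediterranean Sea", "Mediterranean Sea"),
  short_amplicon = c(FALSE, FALSE, TRUE),
  latitude = c(48.77, 41.67, 42.49),
  longitude = c(-3.97, 2.80, 3.14),
  stringsAsFactors = FALSE)

.DATASET_REGIONS <- list(
  ASTAN = "English Channel",
  BBMO = "Mediterranean Sea",
  SOLA = "Mediterranean Sea",
  CAMPAIGN_TROP = "Tropical/Subtropical Ocean",
  CAMPAIGN_MED = "Mediterranean Sea",
  COASTAL = c("English Channel", "Bay of Biscay", "North Sea", "Black Sea"))

.GENUS_POOL <- c("Euduboscquella", "Amoebophrya", "Hematodinium",
                 "Syndinium", "Duboscquella", "Ichthyodinium")

.ORDER_POOL <- c("Dino-Group-I", "Dino-Group-II", "Dino-Group-III",
                 "Dino-Group-V", "Unknown")
.ORDER_PROBS <- c(0.25, 0.55, 0.05, 0.03, 0.12)

#' Specification of a synthetic metabarcoding corpus
#'
#' Collects the tunable parameters of the generator with defaults that
#' emulate the integrated study at desk scale: 40 planted groups of 6-10
#' members plus small decoy groups, ~400 bp amplicons with one 230 bp
#' short-amplicon dataset, six sea regions with pair-sharing dominated by
#' the Mediterranean and the Tropical/Subtropical Ocean, three fortnightly
#' 8-year time series, and planted periodicities of about half a year, one
#' year and one and a half years at a signal-to-noise ratio of 2.
#'
#' @param n_groups Number of planted groups (kept connected components).
#' @param group_size_range Min/max members per kept group (min >= 6).
#' @param n_decoys,decoy_size_range Small groups below the component size
#'   cutoff.
#' @param seq_len_range Master sequence length range in bp.
#' @param short_amplicon_len Length of short-amplicon dataset members.
#' @param regions Region vocabulary.
#' @param years Length of each time series in years.
#' @param rhythmic_fraction Fraction of groups given a periodic series.
#'   One rhythmic group per time-series site is made *dominant* (the
#'   planted community indicator, at `rhythmic_amplitude`); the remaining
#'   rhythmic groups are minor (at `minor_amplitude`), periodic but not
#'   expected to pass the cumulative-RV indicator cut.
#' @param periods_days Pool of planted periods.
#' @param noise_sd Noise standard deviation relative to the rhythmic
#'   amplitude (0.5 gives SNR 2 on the planted sinusoids).
#' @param rhythmic_amplitude Mean abundance of the dominant rhythmic
#'   group at each site, in units of the non-rhythmic baseline; large
#'   enough that the dominant group carries most of the site community
#'   covariance.
#' @param minor_amplitude Mean abundance of minor rhythmic groups.
#' @param occupancy Probability that a member is observed in an eligible
#'   spatial sample / a non-rhythmic series observation.
#' @param unassigned_genus_fraction Fraction of groups with genus
#'   "Unknown".
#' @param n_contaminants Blocklisted / low-identity / short records added
#'   to exercise the homogenization screens.
#' @param seed Integer seed; generation is reproducible given the spec.
#' @return List of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_groups = 40, group_size_range = c(6, 10),
                           n_decoys = 5, decoy_size_range = c(2, 5),
                           seq_len_range = c(380, 460),
                           short_amplicon_len = 230,
                           regions = DEFAULT_REGIONS, years = 8,
                           rhythmic_fraction = 0.125,
                           periods_days = c(182, 365, 548),
                           noise_sd = 0.5, rhythmic_amplitude = 6,
                           minor_amplitude = 1, occupancy = 0.6,
                           unassigned_genus_fraction = 0.9,
                           n_contaminants = 6, seed = 1) {
  stopifnot(n_groups >= 1, group_size_range[1] >= 6,
            group_size_range[2] >= group_size_range[1],
            n_decoys >= 0, decoy_size_range[1] >= 1,
            decoy_size_range[2] < 6,
            seq_len_range[1] > short_amplicon_len,
            short_amplicon_len > 200,
            years >= 1, rhythmic_fraction >= 0, rhythmic_fraction <= 1,
            all(periods_days > 0), noise_sd >= 0,
            rhythmic_amplitude > 0, minor_amplitude > 0,
            occupancy > 0, occupancy <= 1,
            unassigned_genus_fraction >= 0,
            unassigned_genus_fraction <= 1, n_contaminants >= 0)
  structure(list(n_groups = n_groups,
                 group_size_range = group_size_range,
                 n_decoys = n_decoys, decoy_size_range = decoy_size_range,
                 seq_len_range = seq_len_range,
                 short_amplicon_len = short_amplicon_len,
                 regions = regions, years = years,
                 rhythmic_fraction = rhythmic_fraction,
                 periods_days = periods_days, noise_sd = noise_sd,
                 rhythmic_amplitude = rhythmic_amplitude,
                 minor_amplitude = minor_amplitude,
                 occupancy = occupancy,
                 unassigned_genus_fraction = unassigned_genus_fraction,
                 n_contaminants = n_contaminants, seed = seed),
            class = "synthetic_spec")
}

.random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Draw a region combination: sizes follow the sharing profile of the
# integrated study (about a quarter endemic, over half shared between
# exactly two regions -- mostly the Mediterranean and the
# Tropical/Subtropical Ocean -- and a tail up to ubiquity).
.draw_region_set <- function(regions) {
  size <- sample(1:6, 1L,
                 prob = c(0.23, 0.58, 0.12, 0.035, 0.02, 0.015))
  size <- min(size, length(regions))
  med_trop <- c("Mediterranean Sea", "Tropical/Subtropical Ocean")
  if (size == 1L) {
    if (runif(1) < 0.7) sample(med_trop, 1L) else sample(regions, 1L)
  } else if (size == 2L && runif(1) < 0.6 && all(med_trop %in% regions)) {
    med_trop
  } else {
    sort(sample(regions, size))
  }
}

.sampling_dates <- function(years, start_year = 2012) {
  yy <- rep(start_year:(start_year + years - 1L), each = 24L)
  mm <- rep(rep(1:12, each = 2L), times = years)
  dd <- rep(c(5L, 20L), times = 12L * years)
  as.Date(sprintf("%d-%02d-%02d", yy, mm, dd))
}

.env_for <- function(depth_m, date, dcm = FALSE) {
  d <- pmin(depth_m, 1000) / 1000
  doy <- as.integer(format(date, "%j"))
  seasonal <- if (depth_m <= 50) 4 * sin(2 * pi * (doy - 120) / 365) else 0
  c(temperature = 22 - 14 * d + seasonal + rnorm(1, 0, 0.4),
    salinity = 35.2 + 0.5 * d + rnorm(1, 0, 0.15),
    ph = 8.1 - 0.25 * d + rnorm(1, 0, 0.02),
    oxygen = 6 - 2.5 * d + rnorm(1, 0, 0.2),
    no3 = 0.4 + 11 * d + rnorm(1, 0, 0.3),
    no2 = 0.05 + 0.25 * d + abs(rnorm(1, 0, 0.02)),
    nh4 = 0.1 + 0.3 * d + abs(rnorm(1, 0, 0.03)),
    po4 = 0.05 + 0.7 * d + abs(rnorm(1, 0, 0.02)),
    sio4 = 1 + 9 * d + rnorm(1, 0, 0.4),
    chla = max(0.01, (if (dcm) 1.6 else if (depth_m <= 5) 0.6 else 0.05) +
                 rnorm(1, 0, 0.05)))
}

.build_metadata <- function(spec) {
  dates <- .sampling_dates(spec$years)
  rows <- list()
  for (k in seq_len(nrow(.SITES))) {
    site <- .SITES[k, ]
    rows[[site$dataset]] <- data.frame(
      sample_id = sprintf("%s.s%03d", site$dataset, seq_along(dates)),
      dataset = site$dataset, region = site$region,
      station = site$dataset, date = dates, depth_m = 1,
      depth_type = "SRF", size_fraction = "0.2-3um",
      latitude = site$latitude, longitude = site$longitude,
      stringsAsFactors = FALSE)
  }
  layer_depth <- c(SRF = 2, DCM = 60, MESO = 500, BATHY = 2000)
  camp <- list(CAMPAIGN_TROP = list(stations = paste0("T", 1:6),
                                    region = "Tropical/Subtropical Ocean",
                                    lat = -10, lon = -30),
               CAMPAIGN_MED = list(stations = paste0("M", 1:4),
                                   region = "Mediterranean Sea",
                                   lat = 39, lon = 6))
  for (nm in names(camp)) {
    cf <- camp[[nm]]
    grid <- expand.grid(station = cf$stations,
                        depth_type = names(layer_depth),
                        stringsAsFactors = FALSE)
    rows[[nm]] <- data.frame(
      sample_id = sprintf("%s.s%03d", nm, seq_len(nrow(grid))),
      dataset = nm, region = cf$region, station = grid$station,
      date = as.Date("2017-06-15") + seq_len(nrow(grid)),
      depth_m = unname(layer_depth[grid$depth_type]),
      depth_type = grid$depth_type, size_fraction = "0.8-20um",
      latitude = cf$lat + runif(nrow(grid), -5, 5),
      longitude = cf$lon + runif(nrow(grid), -5, 5),
      stringsAsFactors = FALSE)
  }
  coastal_regions <- .DATASET_REGIONS$COASTAL
  grid <- expand.grid(region = coastal_regions,
                      depth_type = c("SRF", "DCM"),
                      stringsAsFactors = FALSE)
  rows[["COASTAL"]] <- data.frame(
    sample_id = sprintf("COASTAL.s%03d", seq_len(nrow(grid))),
    dataset = "COASTAL", region = grid$region,
    station = paste0("C", as.integer(factor(grid$region))),
    date = as.Date("2018-05-10") + seq_len(nrow(grid)),
    depth_m = ifelse(grid$depth_type == "DCM", 40, 1),
    depth_type = grid$depth_type, size_fraction = "0.8-20um",
    latitude = runif(nrow(grid), 40, 60),
    longitude = runif(nrow(grid), -10, 30),
    stringsAsFactors = FALSE)
  md <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  env <- t(mapply(.env_for, md$depth_m, md$date, md$depth_type == "DCM"))
  cbind(md, as.data.frame(env))
}

# Periodic or noise series on the time-series sampling dates; truncated at
# zero like read counts.
.series_for <- function(dates, rhythmic, period, amplitude, spec) {
  n <- length(dates)
  t <- as.numeric(dates)
  if (rhythmic) {
    x <- amplitude *
      (1 + 0.9 * sin(2 * pi * t / period + runif(1, 0, 2 * pi))) +
      rnorm(n, 0, spec$noise_sd * amplitude)
  } else {
    x <- exp(rnorm(n, 0, 0.4)) * (runif(n) < spec$occupancy)
  }
  pmax(x, 0)
}

#' Generate a synthetic metabarcoding corpus with ground truth
#'
#' Builds the six per-dataset inputs (records, abundance, taxonomy), the
#' global sample metadata, and the planted truth (group partition, region
#' sets, rhythmic ids with periods, genus labels). When `dir` is given,
#' the corpus is also written out as `sequences.fasta`, `abundance.tsv`,
#' `metadata.tsv`, `taxonomy.tsv` and `truth.json`.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Optional output directory (created if missing).
#' @return List with `datasets` (named list ready for [harmonize()]),
#'   `metadata` (data.frame), `records`, `taxonomy`, `abundance` (raw,
#'   unnormalized matrix over all samples) and `truth`.
#' @export
generate_synthetic <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  metadata <- .build_metadata(spec)
  samples <- metadata$sample_id
  sample_region <- stats::setNames(metadata$region, samples)
  sample_dataset <- stats::setNames(metadata$dataset, samples)
  ts_dates <- stats::setNames(
    lapply(.SITES$dataset,
           function(d) metadata$date[metadata$dataset == d]),
    .SITES$dataset)

  n_all <- spec$n_groups + spec$n_decoys
  group_ids <- c(sprintf("G%02d", seq_len(spec$n_groups)),
                 if (spec$n_decoys)
                   sprintf("D%02d", seq_len(spec$n_decoys)))
  is_decoy <- startsWith(group_ids, "D")

  ## --- region combinations; make sure every region is represented ----
  region_sets <- lapply(seq_len(n_all),
                        function(i) .draw_region_set(spec$regions))
  names(region_sets) <- group_ids
  uncovered <- setdiff(spec$regions,
                       unique(unlist(region_sets[!is_decoy])))
  if (length(uncovered)) {
    patch <- sample(which(!is_decoy), length(uncovered))
    for (i in seq_along(uncovered)) {
      g <- patch[i]
      region_sets[[g]] <- sort(union(region_sets[[g]], uncovered[i]))
    }
  }

  ## --- rhythmic groups and their home sites --------------------------
  # one *dominant* rhythmic group per time-series site (the planted
  # community indicator); remaining rhythmic groups are minor, each with
  # one home site where its sinusoid is planted
  kept_ids <- group_ids[!is_decoy]
  eligible <- lapply(.SITES$dataset, function(d) {
    r <- .DATASET_REGIONS[[d]]
    kept_ids[vapply(region_sets[kept_ids],
                    function(R) r %in% R, NA)]
  })
  names(eligible) <- .SITES$dataset
  n_rhythmic <- round(spec$rhythmic_fraction * spec$n_groups)
  dominant <- character(0)
  for (d in .SITES$dataset) {
    if (length(dominant) >= n_rhythmic) break
    pool <- setdiff(eligible[[d]], names(dominant))
    if (length(pool)) {
      g <- sample(pool, 1L)
      dominant[g] <- d
    }
  }
  minor_pool <- setdiff(unique(unlist(eligible)), names(dominant))
  minor <- character(0)
  n_minor <- min(max(n_rhythmic - length(dominant), 0L),
                 length(minor_pool))
  if (n_minor > 0L) {
    for (g in sample(minor_pool, n_minor)) {
      sites <- .SITES$dataset[vapply(.SITES$dataset, function(d)
        g %in% eligible[[d]], NA)]
      minor[g] <- sample(sites, 1L)
    }
  }
  rhythmic_home <- c(dominant, minor)   # group id -> home site dataset
  rhythmic_ids <- sort(as.character(names(rhythmic_home)))
  periods <- stats::setNames(
    spec$periods_days[1 + (seq_along(rhythmic_ids) - 1) %%
                        length(spec$periods_days)],
    rhythmic_ids)

  ## --- master sequences with a cross-group dissimilarity guarantee --
  # no cross-group edge is possible when no master pair shares an exact
  # segment reaching 0.8 * short_amplicon_len (the loosest applicable
  # coverage bound, via the asymmetric short-amplicon rule)
  lcs_bound <- ceiling(0.8 * spec$short_amplicon_len) - 1L
  masters <- character(n_all)
  for (i in seq_len(n_all)) {
    repeat {
      cand <- .random_dna(sample(spec$seq_len_range[1]:spec$seq_len_range[2], 1L))
      if (i == 1L) { masters[i] <- cand; break }
      shared <- longest_common_substring(rep(cand, i - 1L),
                                         masters[seq_len(i - 1L)])
      if (max(shared) <= lcs_bound) { masters[i] <- cand; break }
    }
  }

  ## --- members: nested prefixes of the master ------------------------
  # choose, per region of the group, one dataset that samples it
  rec_rows <- list()
  member_dataset <- list()
  partition <- list()
  for (i in seq_len(n_all)) {
    g <- group_ids[i]
    R <- region_sets[[g]]
    ds <- vapply(R, function(r) {
      cov <- .DATASET_REGIONS
      opts <- names(cov)[vapply(cov, function(x) r %in% x, NA)]
      if (is_decoy[i]) {
        spatial <- setdiff(opts, .SITES$dataset)
        if (length(spatial)) opts <- spatial
      }
      if (g %in% rhythmic_ids) {
        home <- rhythmic_home[[g]]
        if (r == .DATASET_REGIONS[[home]]) return(home)
      }
      sample(opts, 1L)
    }, "")
    ds <- unique(unname(ds))
    size <- if (is_decoy[i]) {
      sample(spec$decoy_size_range[1]:spec$decoy_size_range[2], 1L)
    } else {
      sample(spec$group_size_range[1]:spec$group_size_range[2], 1L)
    }
    size <- max(size, length(ds))
    member_ds <- c(ds, sample(ds, size - length(ds), replace = TRUE))
    L <- nchar(masters[i])
    min_len <- ceiling(0.8 * L)
    seqs <- vapply(seq_len(size), function(k) {
      d <- member_ds[k]
      if (d == "SOLA") {
        substr(masters[i], 1L, spec$short_amplicon_len)
      } else if (k == 1L) {
        masters[i]                       # one full copy per group
      } else {
        substr(masters[i], 1L, sample(min_len:L, 1L))
      }
    }, "")
    ids <- sprintf("%s.M%d", g, seq_len(size))
    rec_rows[[g]] <- data.frame(
      id = ids, sequence = seqs, dataset = member_ds,
      short_amplicon = member_ds == "SOLA",
      best_ref_identity = round(runif(size, 80, 100), 1),
      stringsAsFactors = FALSE)
    member_dataset[[g]] <- stats::setNames(member_ds, ids)
    partition[[g]] <- ids
  }

  ## --- taxonomy ------------------------------------------------------
  genus_labels <- stats::setNames(rep(UNKNOWN_LABEL, n_all), group_ids)
  assigned <- runif(n_all) >= spec$unassigned_genus_fraction
  genus_labels[assigned] <- sample(.GENUS_POOL, sum(assigned),
                                   replace = TRUE)
  orders <- stats::setNames(
    sample(.ORDER_POOL, n_all, replace = TRUE, prob = .ORDER_PROBS),
    group_ids)
  tax_rows <- lapply(group_ids, function(g) {
    ids <- partition[[g]]
    data.frame(id = ids, kingdom = "Eukaryota", supergroup = "Alveolata",
               division = "Dinoflagellata", class = "Syndiniales",
               order = orders[[g]], family = UNKNOWN_LABEL,
               genus = genus_labels[[g]], species = UNKNOWN_LABEL,
               stringsAsFactors = FALSE)
  })

  ## --- contaminants exercising the homogenization screens ------------
  contaminant_ids <- character(0)
  if (spec$n_contaminants > 0) {
    kinds <- rep(c("blocklist", "identity", "length"),
                 length.out = spec$n_contaminants)
    ids <- sprintf("X%02d", seq_len(spec$n_contaminants))
    contaminant_ids <- ids
    lens <- ifelse(kinds == "length", 150L, 420L)
    cseq <- vapply(lens, .random_dna, "")
    cds <- sample(setdiff(names(.DATASET_REGIONS), "SOLA"),
                  spec$n_contaminants, replace = TRUE)
    rec_rows[["contaminants"]] <- data.frame(
      id = ids, sequence = cseq, dataset = cds,
      short_amplicon = FALSE,
      best_ref_identity = ifelse(kinds == "identity",
                                 round(runif(spec$n_contaminants, 60, 79), 1),
                                 round(runif(spec$n_contaminants, 85, 100), 1)),
      stringsAsFactors = FALSE)
    tax_rows[["contaminants"]] <- data.frame(
      id = ids, kingdom = "Eukaryota",
      supergroup = ifelse(kinds == "blocklist", "Opisthokonta",
                          "Alveolata"),
      division = ifelse(kinds == "blocklist", "Metazoa",
                        "Dinoflagellata"),
      class = ifelse(kinds == "blocklist", UNKNOWN_LABEL, "Syndiniales"),
      order = UNKNOWN_LABEL, family = UNKNOWN_LABEL,
      genus = UNKNOWN_LABEL, species = UNKNOWN_LABEL,
      stringsAsFactors = FALSE)
  }

  records <- do.call(rbind, c(rec_rows, list(make.row.names = FALSE)))
  taxonomy <- do.call(rbind, c(tax_rows, list(make.row.names = FALSE)))

  ## --- abundance -----------------------------------------------------
  ab <- matrix(0, nrow = nrow(records), ncol = length(samples),
               dimnames = list(records$id, samples))
  for (i in seq_len(n_all)) {
    g <- group_ids[i]
    R <- region_sets[[g]]
    mds <- member_dataset[[g]]
    for (d in unique(mds)) {
      members <- names(mds)[mds == d]
      if (d %in% .SITES$dataset) {
        site_region <- .DATASET_REGIONS[[d]]
        if (!site_region %in% R) next
        at_home <- g %in% rhythmic_ids && rhythmic_home[[g]] == d
        amp <- if (g %in% names(dominant)) spec$rhythmic_amplitude
               else spec$minor_amplitude
        x <- .series_for(ts_dates[[d]], at_home, periods[g], amp, spec)
        cols <- samples[sample_dataset[samples] == d]
        share <- x / length(members)
        for (m in members) ab[m, cols] <- share
      } else {
        cols <- samples[sample_dataset[samples] == d &
                          sample_region[samples] %in% R]
        for (m in members) {
          on <- runif(length(cols)) < spec$occupancy
          ab[m, cols[on]] <- exp(rnorm(sum(on), 0, 0.5))
        }
      }
    }
    # constructive guarantee: the group is observed in every region of
    # its planted combination and nowhere else
    for (r in R) {
      cols <- samples[sample_region[samples] == r &
                        sample_dataset[samples] %in% unique(mds)]
      if (length(cols) && sum(ab[partition[[g]], cols]) == 0) {
        m <- names(mds)[match(sample_dataset[cols[1L]], mds)]
        ab[m, cols[1L]] <- 1
      }
    }
  }
  if (length(contaminant_ids)) {
    for (m in contaminant_ids) {
      d <- records$dataset[records$id == m]
      cols <- samples[sample_dataset[samples] == d]
      on <- sample(cols, min(3L, length(cols)))
      ab[m, on] <- exp(rnorm(length(on), 0, 0.5))
    }
  }
  # every sample must carry signal from at least one planted group
  zero_cols <- colnames(ab)[colSums(ab[!records$id %in% contaminant_ids,
                                       , drop = FALSE]) == 0]
  for (s in zero_cols) {
    r <- sample_region[[s]]
    d <- sample_dataset[[s]]
    for (g in group_ids) {
      if (r %in% region_sets[[g]] && d %in% member_dataset[[g]]) {
        m <- names(member_dataset[[g]])[match(d, member_dataset[[g]])]
        ab[m, s] <- 1
        break
      }
    }
  }

  ## --- assemble ------------------------------------------------------
  datasets <- lapply(names(.DATASET_REGIONS), function(d) {
    rec <- records[records$dataset == d, , drop = FALSE]
    cols <- samples[sample_dataset[samples] == d]
    list(records = rec,
         abundance = ab[rec$id, cols, drop = FALSE],
         taxonomy = taxonomy[taxonomy$id %in% rec$id, , drop = FALSE])
  })
  names(datasets) <- names(.DATASET_REGIONS)

  truth <- list(
    partition = partition[group_ids[!is_decoy]],
    decoy_partition = partition[group_ids[is_decoy]],
    region_sets = region_sets[group_ids[!is_decoy]],
    decoy_region_sets = region_sets[group_ids[is_decoy]],
    rhythmic_ids = rhythmic_ids,
    rhythmic_home = as.list(rhythmic_home),
    indicator_ids = if (length(dominant))
      as.list(stats::setNames(names(dominant), unname(dominant)))
    else structure(list(), names = character()),
    periods_days = as.list(periods),
    genus_labels = as.list(genus_labels[group_ids[!is_decoy]]),
    contaminant_ids = contaminant_ids)

  out <- list(datasets = datasets, metadata = metadata,
              records = records, taxonomy = taxonomy, abundance = ab,
              truth = truth)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_fasta(records, file.path(dir, "sequences.fasta"))
    write_abundance(ab, file.path(dir, "abundance.tsv"))
    md <- metadata
    md$date <- format(md$date)
    write.table(md, file.path(dir, "metadata.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(taxonomy, file.path(dir, "taxonomy.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Disperse substitutions through sequences
#'
#' Introduces regularly spaced substitutions so that the longest exact
#' run shared with the original is bounded by the substitution spacing --
#' a negative control for the edge rule (spacing below 0.8 of the length
#' guarantees no edge to the original).
#'
#' @param records Records data.frame (or data.frame with `sequence`).
#' @param mutation_rate Fraction of positions substituted, in \[0, 1\];
#'   positions are evenly spaced, every `floor(1/rate)` bp.
#' @return The records with mutated sequences.
#' @export
perturb_records <- function(records, mutation_rate) {
  if (mutation_rate < 0 || mutation_rate > 1) {
    stop("mutation_rate must lie in [0, 1]")
  }
  if (mutation_rate == 0) return(records)
  spacing <- max(1L, floor(1 / mutation_rate))
  records$sequence <- vapply(records$sequence, function(s) {
    chars <- strsplit(s, "")[[1L]]
    pos <- seq(spacing, length(chars), by = spacing)
    chars[pos] <- vapply(chars[pos], function(b) {
      sample(setdiff(c("A", "C", "G", "T"), b), 1L)
    }, "")
    paste(chars, collapse = "")
  }, "", USE.NAMES = FALSE)
  records
}
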