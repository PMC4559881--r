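#' @title Seeded synthetic-data generators
#' @description Generators for every input the analysis pipeline consumes
#'   - one-compartment PK profiles in mouse/rat/dog parameter regimes,
#'   sigmoidal dose-response studies, dog CSF biomarker turnover time
#'   courses, and H-DAB-like section images - each returned together with
#'   the generating ground truth so estimators can be tested in closed
#'   loop. Every generator is a pure function of its parameters and seed.
#' @name synthetic_data
NULL

# run code under a seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  set.seed(seed)
  force(code)
}

# multiplicative lognormal noise with a given CV (median-unbiased)
lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  exp(stats::rnorm(n, 0, sqrt(log(1 + cv^2))))
}

#' Species PK parameter presets
#'
#' One-compartment parameter regimes matching the cross-species pattern of
#' the compound's PK: low clearance and short half-life in mouse, higher
#' clearance in rat, and very low clearance with a long half-life in dog.
#' `ke = ln2 / t_half` and `v = cl / ke` (terminal volume convention).
#'
#' @param species `"mouse"`, `"rat"` or `"dog"`.
#' @return List: `cl_ml_min_kg`, `t_half_h`, `f_oral`, `ka`, `ke`,
#'   `v_l_kg`, `dose_iv`, `dose_po` (umol/kg).
#' @export
pk_preset <- function(species = c("mouse", "rat", "dog")) {
  species <- match.arg(species)
  p <- switch(species,
    mouse = list(cl_ml_min_kg = 16,  t_half_h = 3.6,  f_oral = 0.37,
                 ka = 2.0, dose_iv = 2, dose_po = 6),
    rat   = list(cl_ml_min_kg = 52,  t_half_h = 2.7,  f_oral = 0.92,
                 ka = 2.0, dose_iv = 2, dose_po = 6),
    dog   = list(cl_ml_min_kg = 0.4, t_half_h = 36.2, f_oral = 0.62,
                 ka = 1.0, dose_iv = 2, dose_po = 2))
  p$ke <- log(2) / p$t_half_h
  p$v_l_kg <- (p$cl_ml_min_kg * 60 / 1000) / p$ke
  p$species <- species
  p
}

default_pk_times <- function(species) {
  switch(species,
    mouse = c(0.083, 0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 10, 12, 16, 20, 24),
    rat   = c(0.083, 0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 10, 12, 16, 20, 24,
              32, 48),
    dog   = c(0.25, 0.5, 1, 2, 4, 8, 12, 24, 48, 72, 96, 120, 168, 240,
              336, 408))
}

#' Generate a one-compartment PK profile with ground truth
#'
#' Oral profiles follow the closed-form first-order absorption model with
#' scaled dose `F*D/V`; intravenous profiles are mono-exponential `D/V *
#' exp(-ke t)`. Concentration noise is multiplicative lognormal with the
#' given CV.
#'
#' @param species `"mouse"`, `"rat"` or `"dog"` (sets CL, t1/2, F, ka and
#'   the study-like sampling skeleton).
#' @param dose Dose in umol/kg; defaults to the preset's study dose.
#' @param route `"po"` or `"iv"`.
#' @param noise_cv Coefficient of variation of the lognormal noise
#'   (0 = noiseless).
#' @param seed RNG seed (default 0).
#' @param times Optional sampling times (h) overriding the skeleton.
#' @return List with `profile` (a [ct_profile]) and `truth` (generating
#'   parameters, including the preset and seed).
#' @export
gen_pk_profile <- function(species = c("mouse", "rat", "dog"), dose = NULL,
                           route = c("po", "iv"), noise_cv = 0, seed = 0,
                           times = NULL) {
  species <- match.arg(species)
  route <- match.arg(route)
  p <- pk_preset(species)
  if (is.null(dose)) dose <- if (route == "po") p$dose_po else p$dose_iv
  if (is.null(times)) times <- default_pk_times(species)
  conc <- if (route == "po") {
    conc_oral(pk_forcing(p$f_oral * dose / p$v_l_kg, p$ka, p$ke), times)
  } else {
    dose / p$v_l_kg * exp(-p$ke * times)
  }
  conc <- with_seed(seed, conc * lognoise(length(conc), noise_cv))
  list(profile = ct_profile(times = times, conc = conc,
                            subject_id = paste0(species, "_", seed),
                            matrix = "blood", unit = "uM",
                            lloq = 1e-4, dose = dose, route = route),
       truth = c(p, list(dose = dose, route = route,
                         noise_cv = noise_cv, seed = seed)))
}

#' Generate a dose-ranging study with a sigmoidal dose-response
#'
#' Per-animal analyte levels are `baseline * (1 - d^h/(ed50^h + d^h))`
#' under lognormal noise; group means are returned alongside the vehicle
#' group, the input [ed50_from_study()] expects.
#'
#' @param ed50 True half-maximal efficacious dose (umol/kg), default 1.6.
#' @param hill True Hill coefficient, default 1.
#' @param n_per_group Animals per group, default 5.
#' @param noise_cv CV of per-animal lognormal noise, default 0.1.
#' @param doses Dose grid (umol/kg), default 0.3/1/3/10/30.
#' @param baseline Vehicle-group analyte mean (arbitrary units).
#' @param seed RNG seed.
#' @return List: `dose_groups` (named means, input for
#'   [ed50_from_study()]), `vehicle_mean`, `animals` (long data frame) and
#'   `truth`.
#' @export
gen_dose_response <- function(ed50 = 1.6, hill = 1, n_per_group = 5,
                              noise_cv = 0.1,
                              doses = c(0.3, 1, 3, 10, 30),
                              baseline = 0.66, seed = 0) {
  stopifnot(ed50 > 0, n_per_group >= 1, noise_cv >= 0)
  with_seed(seed, {
    all_doses <- c(0, doses)
    animals <- do.call(rbind, lapply(all_doses, function(d) {
      mu <- baseline * (1 - d^hill / (ed50^hill + d^hill))
      data.frame(dose = d,
                 value = mu * lognoise(n_per_group, noise_cv))
    }))
    means <- tapply(animals$value, animals$dose, mean)
    vehicle_mean <- means[["0"]]
    dose_groups <- means[names(means) != "0"]
    list(dose_groups = dose_groups, vehicle_mean = vehicle_mean,
         animals = animals,
         truth = list(ed50 = ed50, hill = hill, baseline = baseline,
                      n_per_group = n_per_group, noise_cv = noise_cv,
                      doses = doses, seed = seed))
  })
}

#' Default dog-study PK forcing (peak blood concentration 0.7 uM)
#'
#' Absorption at 1/h and the dog terminal rate `ln2/36.2` 1/h; the scaled
#' dose is chosen so the closed-form peak equals `cmax`.
#'
#' @param cmax Target peak concentration (uM), default 0.7.
#' @return A [pk_forcing].
#' @export
dog_forcing <- function(cmax = 0.7) {
  ka <- 1.0; ke <- log(2) / 36.2
  tmax <- log(ka / ke) / (ka - ke)
  peak1 <- ka / (ka - ke) * (exp(-ke * tmax) - exp(-ka * tmax))
  pk_forcing(dose_scaled = cmax / peak1, ka = ka, ke = ke)
}

#' Generate a dog CSF-biomarker turnover study with ground truth
#'
#' Emulates a serial-sampling single-dose dog study: predose CSF samples
#' at -24 and -1 h, post-dose sampling to 168 h, a shared blood PK forcing
#' with a ~0.7 uM peak, per-subject baselines drawn lognormally around
#' 6000 pg/ml (between-subject CV 0.2), and the indirect-response model
#' driving suppression to roughly 20 % of baseline with recovery by about
#' 120 h.
#'
#' @param ic50 True in vivo IC50 (uM), default 0.059.
#' @param kout True biomarker clearance rate (1/h), default 0.26.
#' @param imax Maximal inhibition, default 1.
#' @param n_subjects Number of dogs, default 4.
#' @param noise_cv Residual lognormal CV on blood and CSF samples,
#'   default 0.1.
#' @param baseline_mean,baseline_cv Between-subject baseline distribution
#'   (pg/ml), defaults 6000 and 0.2.
#' @param forcing PK forcing; default [dog_forcing()].
#' @param seed RNG seed.
#' @return List: `blood` (list of [ct_profile]), `response` (list of data
#'   frames `time`/`response`), `truth` (parameters incl. per-subject
#'   baselines and the noiseless curves).
#' @export
gen_dog_study <- function(ic50 = 0.059, kout = 0.26, imax = 1,
                          n_subjects = 4, noise_cv = 0.1,
                          baseline_mean = 6000, baseline_cv = 0.2,
                          forcing = dog_forcing(), seed = 0) {
  pk_times <- c(0.5, 1, 2, 4, 8, 12, 24, 48, 72, 96, 120, 168)
  pd_times <- c(-24, -1, 1, 2, 4, 8, 12, 24, 48, 72, 96, 120, 168)
  with_seed(seed, {
    baselines <- baseline_mean * lognoise(n_subjects, baseline_cv)
    blood <- vector("list", n_subjects)
    response <- vector("list", n_subjects)
    clean <- vector("list", n_subjects)
    for (i in seq_len(n_subjects)) {
      cc <- conc_oral(forcing, pk_times)
      blood[[i]] <- ct_profile(
        times = pk_times, conc = cc * lognoise(length(cc), noise_cv),
        subject_id = paste0("dog", i), matrix = "blood", unit = "uM",
        lloq = 1e-3, dose = 1.1, route = "po")
      m <- turnover_model(kin = kout * baselines[i], kout = kout,
                          ic50 = ic50, imax = imax)
      sim <- simulate_turnover(m, forcing, times = pd_times)
      clean[[i]] <- sim
      response[[i]] <- data.frame(
        time = pd_times,
        response = sim$response * lognoise(length(pd_times), noise_cv))
    }
    list(blood = blood, response = response,
         truth = list(ic50 = ic50, kout = kout, imax = imax,
                      forcing = forcing, baselines = baselines,
                      clean_response = clean, noise_cv = noise_cv,
                      seed = seed))
  })
}

## ---- synthetic H-DAB sections ------------------------------------------

# rasterize a disk of approximately `target_area` px centred at (r0, c0);
# returns the index matrix of covered pixels
disk_pixels <- function(r0, c0, target_area, nrow, ncol) {
  radius <- sqrt(target_area / pi)
  rr <- seq(max(1L, floor(r0 - radius)), min(nrow, ceiling(r0 + radius)))
  cc <- seq(max(1L, floor(c0 - radius)), min(ncol, ceiling(c0 + radius)))
  g <- expand.grid(row = rr, col = cc)
  keep <- (g$row - r0)^2 + (g$col - c0)^2 <= radius^2
  as.matrix(g[keep, , drop = FALSE])
}

# pick a disk radius whose rasterized pixel count lands inside [lo, hi]
area_in_class <- function(lo, hi) {
  # uniform in the middle 80 % of the class so rasterization stays inside
  lo + (hi - lo) * (0.1 + 0.8 * stats::runif(1))
}

#' Generate a synthetic H-DAB section image with ground truth
#'
#' Builds an RGB brightfield-like image on a white background:
#' hematoxylin-coloured nuclei disks plus DAB-coloured deposits with pixel
#' areas drawn from the three size classes (granules < 25 px, which the
#' pipeline must reject; intracellular deposits placed adjacent to a
#' nucleus; free-standing small and large plaques), with minimum-distance
#' (Poisson-disk style) placement so objects never overlap and free
#' plaques stay outside every nuclear vicinity. Pixel colours are
#' generated from the same stain OD basis the deconvolution inverts, so a
#' noiseless image round-trips exactly. Optional single-channel
#' fluorescence images carry glia clusters placed near deposits with
#' probability `glia_coupling` (uniformly at random otherwise).
#'
#' @param n_large,n_small,n_granules Deposit counts per class.
#' @param n_nuclei Number of nuclei disks.
#' @param n_intracellular Deposits planted inside a nuclear vicinity
#'   (classified intracellular by proximity), default 0.
#' @param glia_coupling Probability in `[0, 1]` that a glia cluster is
#'   planted next to a deposit rather than uniformly at random.
#' @param n_glia Clusters per fluorescence channel (named vector
#'   `c(gfap =, iba1 =)`); default scales with the plaque count.
#' @param dims Image `c(rows, cols)`, default 640 x 640.
#' @param stain_od Peak stain amount (OD units) of drawn objects.
#' @param seed RNG seed.
#' @return List: `image` (RGB array), `roi_mask`, `gfap`, `iba1`
#'   (fluorescence matrices) and `truth` (masks, per-deposit table with
#'   planted categories, glia centres, parameters, seed).
#' @export
gen_section_image <- function(n_large = 5, n_small = 20, n_granules = 30,
                              n_nuclei = 60, n_intracellular = 0,
                              glia_coupling = 1, n_glia = NULL,
                              dims = c(640, 640), stain_od = 1.0, seed = 0) {
  nr <- dims[1L]; nc <- dims[2L]
  vicinity <- 5
  if (is.null(n_glia)) {
    n_cl <- max(1L, n_large + round(n_small / 2))
    n_glia <- c(gfap = n_cl, iba1 = n_cl)
  }
  with_seed(seed, {
    occupied_r <- numeric(0); occupied_c <- numeric(0); occupied_rad <- numeric(0)
    place <- function(radius, margin, near = NULL, near_gap = NULL,
                      trials = 4000) {
      for (trial in seq_len(trials)) {
        if (is.null(near)) {
          r0 <- stats::runif(1, radius + 2, nr - radius - 2)
          c0 <- stats::runif(1, radius + 2, nc - radius - 2)
        } else {
          ang <- stats::runif(1, 0, 2 * pi)
          d <- near$radius + near_gap + radius
          r0 <- near$r + d * cos(ang); c0 <- near$c + d * sin(ang)
          if (r0 < radius + 2 || r0 > nr - radius - 2 ||
              c0 < radius + 2 || c0 > nc - radius - 2) next
        }
        if (length(occupied_r)) {
          dd <- sqrt((occupied_r - r0)^2 + (occupied_c - c0)^2)
          req <- occupied_rad + radius + margin
          if (!is.null(near)) {
            i_near <- which(occupied_r == near$r & occupied_c == near$c)
            if (length(i_near)) req[i_near] <- 0   # anchor overlap handled by near_gap
          }
          if (any(dd < req)) next
        }
        occupied_r <<- c(occupied_r, r0)
        occupied_c <<- c(occupied_c, c0)
        occupied_rad <<- c(occupied_rad, radius)
        return(list(r = r0, c = c0, radius = radius))
      }
      NULL
    }
    # anchored placement: retry with a freshly drawn anchor on failure
    place_near <- function(radius, margin, anchors, near_gap) {
      for (attempt in 1:300) {
        a <- anchors[[sample.int(length(anchors), 1)]]
        pos <- place(radius, margin, near = a, near_gap = near_gap,
                     trials = 60)
        if (!is.null(pos)) return(pos)
      }
      stop("could not place anchored object; reduce counts or enlarge image")
    }

    h_amount <- matrix(0, nr, nc)
    d_amount <- matrix(0, nr, nc)
    nuclei_mask <- matrix(FALSE, nr, nc)
    deposit_lab <- matrix(0L, nr, nc)

    nuclei <- vector("list", n_nuclei)
    for (i in seq_len(n_nuclei)) {
      area <- area_in_class(60, 160)
      pos <- place(sqrt(area / pi), margin = 2 * vicinity + 4)
      px <- disk_pixels(pos$r, pos$c, area, nr, nc)
      nuclei_mask[px] <- TRUE
      h_amount[px] <- stain_od
      nuclei[[i]] <- pos
    }

    deposits <- data.frame(id = integer(), area_px = integer(),
                           category = character(), row = numeric(),
                           col = numeric(), stringsAsFactors = FALSE)
    id <- 0L
    add_deposit <- function(area, category, anchors = NULL, near_gap = NULL) {
      radius <- sqrt(area / pi)
      pos <- if (is.null(anchors)) {
        place(radius, margin = 2 * vicinity + 4)
      } else {
        place_near(radius, margin = 4, anchors = anchors, near_gap = near_gap)
      }
      if (is.null(pos))
        stop("could not place object without overlap; reduce counts or enlarge image")
      px <- disk_pixels(pos$r, pos$c, area, nr, nc)
      id <<- id + 1L
      d_amount[px] <<- stain_od
      deposit_lab[px] <<- id
      deposits[nrow(deposits) + 1L, ] <<-
        list(id, nrow(px), category, pos$r, pos$c)
    }
    for (i in seq_len(n_large)) add_deposit(area_in_class(1100, 2200), "large_plaque")
    for (i in seq_len(n_small)) add_deposit(area_in_class(250, 950), "small_plaque")
    for (i in seq_len(n_intracellular))
      add_deposit(area_in_class(80, 180), "intracellular",
                  anchors = nuclei, near_gap = 1)
    for (i in seq_len(n_granules)) add_deposit(area_in_class(5, 18), "granule")

    stains <- hdab_stain_vectors()
    od <- array(0, c(nr, nc, 3))
    for (ch in 1:3)
      od[, , ch] <- h_amount * stains["hematoxylin", ch] +
                    d_amount * stains["dab", ch]
    image <- 10^(-od)

    roi_mask <- matrix(TRUE, nr, nc)

    gen_channel <- function(n_clusters) {
      chan <- matrix(0.05, nr, nc)
      centres <- data.frame(row = numeric(), col = numeric())
      candidates <- deposits[deposits$category != "granule", , drop = FALSE]
      anchor_list <- lapply(seq_len(nrow(candidates)), function(k)
        list(r = candidates$row[k], c = candidates$col[k],
             radius = sqrt(candidates$area_px[k] / pi)))
      for (i in seq_len(n_clusters)) {
        coupled <- length(anchor_list) > 0 && stats::runif(1) < glia_coupling
        pos <- if (coupled) {
          place_near(5, margin = 4, anchors = anchor_list, near_gap = 3)
        } else {
          place(5, margin = 4)
        }
        if (is.null(pos))
          stop("could not place glia cluster; reduce counts or enlarge image")
        px <- disk_pixels(pos$r, pos$c, 70, nr, nc)
        chan[px] <- 0.9
        centres[nrow(centres) + 1L, ] <- list(pos$r, pos$c)
      }
      list(channel = chan, centres = centres)
    }
    gf <- gen_channel(n_glia[["gfap"]])
    ib <- gen_channel(n_glia[["iba1"]])

    list(image = image, roi_mask = roi_mask,
         gfap = gf$channel, iba1 = ib$channel,
         truth = list(
           nuclei_mask = nuclei_mask, deposit_labels = deposit_lab,
           deposits = deposits,
           counts = c(intracellular = n_intracellular,
                      small_plaque = n_small, large_plaque = n_large,
                      granule = n_granules),
           glia_centres = list(gfap = gf$centres, iba1 = ib$centres),
           params = list(n_large = n_large, n_small = n_small,
                         n_granules = n_granules, n_nuclei = n_nuclei,
                         n_intracellular = n_intracellular,
                         glia_coupling = glia_coupling, n_glia = n_glia,
                         dims = dims, stain_od = stain_od),
           seed = seed))
  })
}
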