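# Synthetic study generator.
#
# Produces complete study inputs (EEG recordings with event markers +
# behavioral data) with known ground truth. Designed band coherence between
# chosen channel pairs is obtained by mixing a shared band-limited source S
# into both channels on top of independent band noise:
#   x_i = a_i S + N_i,  x_j = a_j S + N_j
# With equal in-band spectra for S and the N's, the theoretical
# magnitude-squared coherence is
#   gamma^2(f) = [a_i^2/(a_i^2+1)] * [a_j^2/(a_j^2+1)]
# so a single pair with target g uses a_i = a_j = sqrt(sqrt(g)/(1-sqrt(g))).
# When several designed pairs share a channel within one (task, band), one
# shared source per connected component is used and the per-channel mixing
# fractions r_c = a_c^2/(a_c^2+1) are solved on the component's tree
# (r_root = max over incident edges of sqrt(g); r_child = g_edge/r_parent),
# which degenerates to the closed form above for isolated pairs.

#' Designed coherence contrasts of the default synthetic cohort
#'
#' One row per (channel pair, band, task) with the target band coherence for
#' the experienced and the novice group. The default set mirrors the
#' magnitudes of the reported expert-novice contrasts: lower frontal theta /
#' alpha coherence but higher fronto-parietal coupling for the experienced
#' group while reading, higher frontal theta/beta/gamma coherence while
#' answering the prepared case, and uniformly higher novice coherence on the
#' unprepared case.
#'
#' @return data.frame with columns `ch1`, `ch2`, `band`, `task`,
#'   `cohExperienced`, `cohNovice`.
#' @export
defaultEffectTable <- function() {
  tab <- rbind(
    c("FC5", "FC6", "theta", "reading", 0.13, 0.52),
    c("P7",  "F8",  "theta", "reading", 0.30, 0.03),
    c("F7",  "FC6", "alpha", "reading", 0.19, 0.52),
    c("FC5", "FC6", "alpha", "reading", 0.20, 0.51),
    c("O1",  "T8",  "gamma", "reading", 0.11, 0.41),
    c("P8",  "F8",  "gamma", "reading", 0.68, 0.32),
    c("F7",  "F8",  "theta", "answer1", 0.40, 0.14),
    c("F7",  "F8",  "beta",  "answer1", 0.53, 0.27),
    c("F7",  "F8",  "gamma", "answer1", 0.51, 0.22),
    c("P7",  "T8",  "gamma", "answer1", 0.17, 0.50),
    c("F3",  "T7",  "beta",  "answer2", 0.11, 0.40),
    c("F3",  "T7",  "gamma", "answer2", 0.06, 0.44),
    c("O1",  "T8",  "gamma", "answer2", 0.07, 0.34),
    c("O1",  "FC6", "gamma", "answer2", 0.05, 0.31),
    c("O1",  "F4",  "gamma", "answer2", 0.15, 0.46),
    c("O1",  "AF4", "gamma", "answer2", 0.05, 0.30))
  data.frame(ch1 = tab[, 1], ch2 = tab[, 2], band = tab[, 3], task = tab[, 4],
             cohExperienced = as.numeric(tab[, 5]),
             cohNovice = as.numeric(tab[, 6]), stringsAsFactors = FALSE)
}

#' Default behavioral linear model of the synthetic cohort
#'
#' Performance and cognitive load (as fractions of their scales) are linear
#' in named normalized features plus Gaussian noise. The performance model
#' loads on designed connectivity contrasts so that the groups separate to
#' roughly 90% vs 50%; the cognitive-load model loads on features without a
#' designed group contrast so both groups report similar load. Checklist
#' ratings for two raters are derived from performance with additive rater
#' noise.
#'
#' @return list with elements `performance`, `tlx` (each: `intercept`,
#'   named `coef`, `noiseSD` on the 0-1 scale), `raterNoise` (SD on the 0-2
#'   rating scale), `nItems`, `itemWeights`.
#' @export
defaultBehaviorModel <- function() {
  list(
    performance = list(
      intercept = 0.60,
      coef = c("answer1.beta.coh.F7-F8" = 0.30,
               "answer2.gamma.coh.F3-T7" = -0.22,
               "reading.gamma.coh.P8-F8" = 0.10),
      noiseSD = 0.05),
    tlx = list(
      intercept = 0.594,
      coef = c("answer1.theta.coh.F4-F8" = 0.168,
               "answer2.theta.coh.F7-AF4" = -0.253,
               "answer2.alpha.psd.F3" = 0.123),
      noiseSD = 0.04),
    raterNoise = 0.25, nItems = 10,
    itemWeights = c(3, 2, 2, 2, 1, 1, 1, 1, 1, 1))
}

#' Configure a synthetic cohort
#'
#' Defaults are the study conditions: two groups of 8, 256 Hz, an 18-minute
#' session preceded by a 3-minute eyes-open baseline (segments 180, 180,
#' 720, 180 s), the designed coherence contrasts of
#' [defaultEffectTable()], pink-noise background with a low-amplitude
#' posterior alpha rhythm, 10% artifact-contaminated epochs, and the
#' behavioral model of [defaultBehaviorModel()].
#'
#' @param nPerGroup participants per group.
#' @param samplingRate Hz.
#' @param segmentDurations seconds for eyes open / reading / answer 1 /
#'   answer 2 (in that order).
#' @param effectTable designed coherence targets (see
#'   [defaultEffectTable()]).
#' @param background list: `alpha` 1/f exponent, `sd` background SD in uV,
#'   `alphaAmp` posterior 10 Hz rhythm SD in uV, `alphaChannels`.
#' @param artifactRate fraction of epochs to contaminate, in [0, 1).
#' @param behaviorModel see [defaultBehaviorModel()].
#' @param seed master seed (integer).
#' @return A [CohortConfig-class].
#' @examples
#' cfg <- cohortConfig(seed = 7)
#' cfg
#' @export
cohortConfig <- function(nPerGroup = 8, samplingRate = 256,
                         segmentDurations = c(180, 180, 720, 180),
                         effectTable = defaultEffectTable(),
                         background = list(alpha = 1, sd = 10, alphaAmp = 3,
                                           alphaChannels = c("O1", "O2", "P7", "P8")),
                         artifactRate = 0.10,
                         behaviorModel = defaultBehaviorModel(),
                         seed = 1) {
  plan <- data.frame(label = unname(.taskMarkers), duration = segmentDurations,
                     stringsAsFactors = FALSE)
  new("CohortConfig", nPerGroup = nPerGroup, samplingRate = samplingRate,
      segmentPlan = plan, effectTable = effectTable,
      background = background, artifactRate = artifactRate,
      behaviorModel = behaviorModel, seed = seed)
}

# deterministic per-participant seed fan-out (kept below 2^31)
.fanSeed <- function(seed, participantIndex, salt = 0) {
  (seed * 1000003 + participantIndex * 7919 + salt * 104729) %% 2147483629
}

# positive-frequency bin indices (1-based, DC = 1) with lo <= f <= hi
.posBins <- function(n, fs, lo, hi) {
  klo <- max(2L, as.integer(ceiling(lo * n / fs - 1e-9)) + 1L)
  khi <- min(as.integer(floor(n / 2)),       # exclude DC and Nyquist
             as.integer(floor(hi * n / fs + 1e-9)) + 1L)
  if (khi < klo) integer() else seq.int(klo, khi)
}

# draw a Hermitian spectrum on the given positive bins (per-bin amplitude
# `amps`, E|z|^2 = amps^2) and return the real time series; expected
# variance is 2 * sum(amps^2) / n^2
.spectralDraw <- function(n, bins, amps) {
  z <- complex(real = rnorm(length(bins), 0, sqrt(0.5)),
               imaginary = rnorm(length(bins), 0, sqrt(0.5))) * amps
  spec <- vector("complex", n)
  spec[bins] <- z
  spec[n + 2 - bins] <- Conj(z)
  Re(fft(spec, inverse = TRUE)) / n
}

# 1/f^alpha background spectrum (bins + amplitudes) restricted to the
# acquisition passband; expected time-domain SD = sdTarget
.backgroundSpectrum <- function(n, fs, alpha, sdTarget, passband = c(0.2, 45)) {
  bins <- .posBins(n, fs, passband[1], passband[2])
  shape <- 1 / pmax((bins - 1) * fs / n, passband[1])^(alpha / 2)
  list(bins = bins, amps = shape * (sdTarget * n / sqrt(2 * sum(shape^2))))
}

# Solve per-channel mixing fractions r_c for one (task, band) effect set.
# Returns list(components), each: channels, r (named), edges (data.frame).
.solveCouplings <- function(edges) {
  edges <- edges[edges$g > 0, , drop = FALSE]
  if (!nrow(edges)) return(list())
  chans <- unique(c(edges$ch1, edges$ch2))
  adj <- lapply(setNames(vector("list", length(chans)), chans), function(x) x)
  for (i in seq_len(nrow(edges))) {
    adj[[edges$ch1[i]]] <- c(adj[[edges$ch1[i]]], i)
    adj[[edges$ch2[i]]] <- c(adj[[edges$ch2[i]]], i)
  }
  seen <- setNames(rep(FALSE, length(chans)), chans)
  comps <- list()
  for (start in chans) {
    if (seen[[start]]) next
    queue <- start; comp <- character(); eidx <- integer()
    seen[[start]] <- TRUE
    while (length(queue)) {
      c0 <- queue[1]; queue <- queue[-1]
      comp <- c(comp, c0)
      for (i in adj[[c0]]) {
        eidx <- c(eidx, i)
        other <- setdiff(c(edges$ch1[i], edges$ch2[i]), c0)
        if (!seen[[other]]) { seen[[other]] <- TRUE; queue <- c(queue, other) }
      }
    }
    eidx <- unique(eidx)
    if (length(eidx) != length(comp) - 1)
      stop("designed effect graph has a cycle within one (task, band); ",
           "only tree-shaped effect sets are supported")
    sub <- edges[eidx, , drop = FALSE]
    deg <- table(c(sub$ch1, sub$ch2))
    root <- names(deg)[which.max(deg)]
    r <- setNames(rep(NA_real_, length(comp)), comp)
    inc <- sub$ch1 == root | sub$ch2 == root
    r[root] <- max(sqrt(sub$g[inc]))
    queue <- root
    while (length(queue)) {
      c0 <- queue[1]; queue <- queue[-1]
      for (i in seq_len(nrow(sub))) {
        if (sub$ch1[i] != c0 && sub$ch2[i] != c0) next
        other <- setdiff(c(sub$ch1[i], sub$ch2[i]), c0)
        if (!is.na(r[other])) next
        r[other] <- sub$g[i] / r[c0]
        queue <- c(queue, other)
      }
    }
    if (any(r >= 1) || any(r < 0))
      stop("infeasible coherence targets within one (task, band): a mixing ",
           "fraction left [0, 1)")
    comps[[length(comps) + 1]] <- list(channels = comp, r = r, edges = sub)
  }
  comps
}

#' Simulate one participant's recording
#'
#' Generates 14 channels of 1/f background (plus a low-amplitude posterior
#' alpha rhythm), then, for every designed effect of the participant's
#' group, replaces the in-band content of the involved channels during the
#' relevant task segment by the shared-source mixture that attains the
#' target band coherence. Deterministic in (config seed, participant index).
#'
#' @param config a [CohortConfig-class].
#' @param participantIndex integer, unique within the cohort.
#' @param group `"novice"` or `"experienced"`.
#' @return list with `recording` ([Recording-class]) and `groundTruth`
#'   (list: `couplings` data.frame, `seed`, `group`; artifact indices are
#'   appended by [injectArtifacts()]).
#' @export
simulateRecording <- function(config, participantIndex,
                              group = c("novice", "experienced")) {
  validObject(config)
  group <- match.arg(group)
  fs <- config@samplingRate
  plan <- config@segmentPlan
  n <- as.integer(round(fs * sum(plan$duration)))
  seed <- .fanSeed(config@seed, participantIndex,
                   salt = ifelse(group == "experienced", 1, 2))
  set.seed(seed)

  bg <- config@background
  chans <- montageChannels()
  sig <- matrix(0, length(chans), n, dimnames = list(chans, NULL))
  spec <- .backgroundSpectrum(n, fs, bg$alpha, bg$sd)
  # posterior alpha rhythm: extra variance on the 9-11 Hz bins (adding two
  # independent Gaussian spectra = one draw with summed per-bin variance)
  rb <- .posBins(n, fs, 9, 11)
  rhythmAmps <- spec$amps
  rhythmAmps[match(rb, spec$bins)] <-
    sqrt(rhythmAmps[match(rb, spec$bins)]^2 +
         (bg$alphaAmp * n)^2 / (2 * length(rb)))
  for (ch in seq_along(chans))
    sig[ch, ] <- .spectralDraw(n, spec$bins,
                               if (chans[ch] %in% bg$alphaChannels)
                                 rhythmAmps else spec$amps)

  onsets <- cumsum(c(0, plan$duration[-nrow(plan)]))
  names(onsets) <- names(.taskMarkers)[match(.normalizeLabel(plan$label),
                                             .taskMarkers)]
  bands <- eegBands()
  et <- config@effectTable
  et$g <- if (group == "experienced") et$cohExperienced else et$cohNovice
  couplings <- list()
  guard <- 3                        # Hz cleared around each injected band so
                                    # window leakage cannot dilute edge bins
  if (nrow(et)) {
    for (grp in split(et, et$task, drop = TRUE)) {
      task <- grp$task[1]
      segIdx <- which(names(onsets) == task)
      if (!length(segIdx)) stop("effect table names unknown task: ", task)
      s0 <- as.integer(round(onsets[segIdx] * fs))
      m <- as.integer(round(plan$duration[segIdx] * fs))
      span <- (s0 + 1):(s0 + m)

      byBand <- split(grp, grp$band, drop = TRUE)
      comps <- lapply(byBand, .solveCouplings)
      inBins <- lapply(names(byBand), function(bd) {
        b <- bands[bands$band == bd, ]
        if (!nrow(b)) stop("effect table names unknown band: ", bd)
        .posBins(m, fs, b$lo, b$hi)
      })
      names(inBins) <- names(byBand)
      guardBins <- lapply(names(byBand), function(bd) {
        b <- bands[bands$band == bd, ]
        .posBins(m, fs, max(b$lo - guard, 0.01), b$hi + guard)
      })
      names(guardBins) <- names(byBand)

      involved <- unique(unlist(lapply(comps, lapply, `[[`, "channels")))
      Z <- list(); removedPow <- list()
      for (ch in involved) {
        z <- fft(sig[ch, span])
        myBands <- names(byBand)[vapply(comps, function(cl)
          any(vapply(cl, function(cp) ch %in% cp$channels, TRUE)), TRUE)]
        for (bd in myBands)
          removedPow[[paste(bd, ch)]] <-
            2 * sum(Mod(z[inBins[[bd]]])^2) / m^2
        kill <- unique(unlist(guardBins[myBands]))
        z[kill] <- 0; z[m + 2 - kill] <- 0
        Z[[ch]] <- z
      }

      for (bd in names(byBand)) {
        pos <- inBins[[bd]]; nb <- length(pos)
        for (comp in comps[[bd]]) {
          sigma <- sqrt(max(mean(unlist(
            removedPow[paste(bd, comp$channels)])), 1e-12))
          amp <- sigma * m / sqrt(2 * nb)
          zS <- complex(real = rnorm(nb, 0, sqrt(0.5)),
                        imaginary = rnorm(nb, 0, sqrt(0.5)))
          for (ch in comp$channels) {
            a <- sqrt(comp$r[ch] / (1 - comp$r[ch]))
            zN <- complex(real = rnorm(nb, 0, sqrt(0.5)),
                          imaginary = rnorm(nb, 0, sqrt(0.5)))
            add <- amp * (a * zS + zN)
            Z[[ch]][pos] <- Z[[ch]][pos] + add
            Z[[ch]][m + 2 - pos] <- Z[[ch]][m + 2 - pos] + Conj(add)
            couplings[[length(couplings) + 1]] <-
              data.frame(task = task, band = bd, channel = ch,
                         r = unname(comp$r[ch]), a = a)
          }
        }
      }
      for (ch in involved)
        sig[ch, span] <- Re(fft(Z[[ch]], inverse = TRUE)) / m
    }
  }

  rec <- newRecording(sig, chans, fs,
                      markers = data.frame(label = plan$label,
                                           onset = unname(onsets)),
                      meta = list(participant = participantIndex,
                                  group = group, seed = seed))
  gt <- list(couplings = if (length(couplings)) do.call(rbind, couplings)
             else data.frame(),
             seed = seed, group = group, artifactEpochs = integer())
  list(recording = rec, groundTruth = gt)
}

#' Contaminate a fraction of epochs with movement-like transients
#'
#' Adds a 0.5-second raised-cosine transient (500 uV peak, well above 5x
#' the background SD) to 2 random channels of each selected 1-second epoch,
#' emulating head/muscle movement artifacts. Deterministic under `seed`.
#'
#' @param recording a [Recording-class].
#' @param rate fraction of epochs to contaminate, in [0, 1).
#' @param seed integer seed.
#' @param amplitude transient peak in microvolts.
#' @return list: `recording` (contaminated copy) and `epochs` (sorted
#'   1-based indices of contaminated 1-second epochs).
#' @export
injectArtifacts <- function(recording, rate, seed, amplitude = 500) {
  if (rate < 0 || rate >= 1) stop("artifact rate must lie in [0, 1)")
  if (rate == 0) return(list(recording = recording, epochs = integer()))
  fs <- recording@samplingRate
  nEp <- floor(recordingDuration(recording))
  k <- round(rate * nEp)
  set.seed(seed)
  idx <- sort(sample.int(nEp, k))
  halfSec <- as.integer(round(fs / 2))
  pulse <- amplitude * 0.5 * (1 - cos(2 * pi * seq_len(halfSec) / halfSec))
  sig <- recording@signal
  nch <- nrow(sig)
  for (e in idx) {
    off <- as.integer((e - 1) * fs + fs / 4)
    span <- (off + 1):(off + halfSec)
    chs <- sample.int(nch, 2)
    sgn <- sample(c(-1, 1), 2, replace = TRUE)
    for (j in 1:2)
      sig[chs[j], span] <- sig[chs[j], span] + sgn[j] * pulse
  }
  recording@signal <- sig
  list(recording = recording, epochs = idx)
}

#' Simulate a complete cohort of recordings
#'
#' One recording per participant (novices then experienced), each with
#' artifacts injected at the configured rate.
#'
#' @param config a [CohortConfig-class].
#' @return list: `recordings` (named list), `groups` (character),
#'   `groundTruth` (per-participant list incl. `artifactEpochs`).
#' @examples
#' cfg <- cohortConfig(nPerGroup = 2, segmentDurations = c(5, 5, 10, 5),
#'                     seed = 1)
#' cohort <- simulateCohort(cfg)
#' names(cohort$recordings)
#' @export
simulateCohort <- function(config) {
  validObject(config)
  groups <- rep(c("novice", "experienced"), each = config@nPerGroup)
  ids <- paste0(ifelse(groups == "novice", "nov", "exp"),
                rep(seq_len(config@nPerGroup), 2))
  recordings <- vector("list", length(ids))
  truth <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sim <- simulateRecording(config, i, groups[i])
    art <- injectArtifacts(sim$recording, config@artifactRate,
                           seed = .fanSeed(config@seed, i, salt = 13))
    sim$groundTruth$artifactEpochs <- art$epochs
    recordings[[i]] <- art$recording
    truth[[i]] <- sim$groundTruth
  }
  names(recordings) <- names(truth) <- ids
  list(recordings = recordings, groups = groups, groundTruth = truth)
}

#' Simulate behavioral outcomes from extracted features
#'
#' Performance (fraction of the checklist's possible score) and cognitive
#' load (fraction of the 0-120 scale) are linear in named normalized
#' features plus Gaussian noise, clipped to [0, 1]. Six TLX subscales are
#' drawn around the intended total and re-summed, and two raters' checklist
#' item ratings (0/1/2) are derived from performance with additive rater
#' noise, enabling inter-rater reliability tests.
#'
#' @param config a [CohortConfig-class] (its `behaviorModel` is used).
#' @param features a normalized [FeatureTable-class] for the cohort.
#' @param seed integer seed.
#' @return list: `behavior` (data.frame: participant, group, performance,
#'   tlx1..tlx6, tlxTotal, tlxFraction), `checklist` (long data.frame:
#'   participant, rater, item, weight, rating), `raterScores` (participants
#'   x 2 matrix of weighted percents), `truth` (the generating model).
#' @export
simulateBehavior <- function(config, features, seed = config@seed) {
  bm <- config@behaviorModel
  X <- assay(features)
  for (nm in c(names(bm$performance$coef), names(bm$tlx$coef)))
    if (!nm %in% rownames(X))
      stop("behavior model names unknown feature: ", nm)
  set.seed(.fanSeed(seed, 0, salt = 29))
  nP <- ncol(X)
  lin <- function(m) as.numeric(m$intercept +
    crossprod(X[names(m$coef), , drop = FALSE], m$coef) +
    rnorm(nP, 0, m$noiseSD))
  clip01 <- function(x) pmin(1, pmax(0, x))
  perf <- clip01(lin(bm$performance))
  tlxFrac0 <- clip01(lin(bm$tlx))
  sub <- vapply(seq_len(nP), function(p)
    pmin(20, pmax(0, tlxFrac0[p] * 120 / 6 + rnorm(6, 0, 1.5))), numeric(6))
  tlxTotal <- colSums(sub)

  w <- bm$itemWeights
  if (length(w) != bm$nItems) w <- rep_len(w, bm$nItems)
  difficulty <- rnorm(bm$nItems, 0, 0.15)
  checklist <- list()
  raterScores <- matrix(NA_real_, nP, 2,
                        dimnames = list(colnames(X), c("rater1", "rater2")))
  for (p in seq_len(nP)) {
    sTrue <- 2 * clip01(perf[p] + difficulty)
    for (rater in 1:2) {
      rating <- round(pmin(2, pmax(0, sTrue + rnorm(bm$nItems, 0, bm$raterNoise))))
      checklist[[length(checklist) + 1]] <- data.frame(
        participant = colnames(X)[p], rater = paste0("rater", rater),
        item = seq_len(bm$nItems), weight = w, rating = rating)
      raterScores[p, rater] <- weightedPercent(w, rating)
    }
  }
  behavior <- data.frame(participant = colnames(X),
                         group = colData(features)$group,
                         performance = perf,
                         t(sub), tlxTotal = tlxTotal,
                         tlxFraction = tlxTotal / 120)
  names(behavior)[4:9] <- paste0("tlx", 1:6)
  list(behavior = behavior, checklist = do.call(rbind, checklist),
       raterScores = raterScores, truth = bm)
}
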