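#' @include AllClasses.R simulate.R preprocess.R quality.R hrf.R correct.R
#' @include glm.R evaluate.R metrics.R spatial.R bayes.R
NULL

.METHODS <- c("NO_SAC", "CAR", "GCR", "SSR", "GLM_ALL", "GLM_BH")
.TASKS <- c("SIM", "ME_LEFT", "ME_RIGHT", "MI")

# ground-truth injection map: 100% / 50% amplitude channels per task ROI
.INJECTION_BY_TASK <- list(
  SIM      = c("6" = 10, "8" = 5),    # M1 left
  ME_RIGHT = c("6" = 10, "8" = 5),    # M1 left
  ME_LEFT  = c("10" = 10, "12" = 5),  # M1 right
  MI       = c("1" = 10, "3" = 5))    # SMA

#' Configuration of a full synthetic comparison run
#'
#' @param nSubjects synthetic cohort size.
#' @param seed master seed; every per-subject and per-stage seed derives
#'   from it.
#' @param age subject age in years.
#' @param sa an [SAParams-class] describing the systemic interference.
#' @param nTrialsSim trials of the semisimulated (SIM) session.
#' @param nTrialsReal trials per task of the multi-task session.
#' @param solver GLM solver for corrections and task GLMs.
#' @param maxAROrder maximum AR order of the AR_IRLS solver.
#' @param hbrFraction deoxy/oxy amplitude ratio of the injected HRFs.
#' @return a named configuration list.
#' @export
reportConfig <- function(nSubjects = 6, seed = 1, age = 65,
                         sa = saParams(), nTrialsSim = 5, nTrialsReal = 5,
                         solver = "AR_IRLS", maxAROrder = 32L,
                         hbrFraction = 1 / 3) {
  list(nSubjects = nSubjects, seed = as.integer(seed), age = age, sa = sa,
       nTrialsSim = nTrialsSim, nTrialsReal = nTrialsReal, solver = solver,
       maxAROrder = maxAROrder, hbrFraction = hbrFraction)
}

# preprocess a raw recording into band-passed concentration data with
# semisimulated HRFs injected per task
.preprocessDataset <- function(rec, schedule, tasks, hbrFraction) {
  qr <- assessChannelQuality(rec)
  od <- pruneChannels(intensityToOD(rec), qr)
  od <- tddr(od)
  hemo <- odToHemoglobin(od)
  for (task in tasks) {
    onsets <- trialOnsets(schedule, task)
    if (!length(onsets)) next
    sub <- new("TrialSchedule", task = task,
               events = data.frame(onset = onsets,
                                   duration = schedule@taskDuration,
                                   label = task),
               taskDuration = schedule@taskDuration, seed = schedule@seed)
    hemo <- injectCanonicalHRF(
      hemo, sub, hrfSpec(amplitudes = .INJECTION_BY_TASK[[task]],
                         hbrFraction = hbrFraction))
  }
  list(hemo = bandpassHemo(hemo), quality = qr)
}

# all six corrections of one band-passed dataset
.allCorrections <- function(hemo, layout, solver, maxAROrder) {
  list(
    NO_SAC = correctNone(hemo),
    CAR = correctCAR(hemo),
    GCR = correctGCR(hemo, buildGCRKernel(layout)),
    SSR = correctSSR(hemo, layout),
    GLM_ALL = correctGLMSDC(hemo, "ALL", solver = solver,
                            maxAROrder = maxAROrder),
    GLM_BH = correctGLMSDC(hemo, "BH", solver = solver,
                           maxAROrder = maxAROrder))
}

# simulate and fully process one subject; returns task GLM betas, selected
# channels, per-trial metrics and per-subject correlation matrices
.processSubject <- function(subject, layout, config, seeds) {
  sa <- config$sa
  schedSim <- makeTrialSchedule("SIM", config$nTrialsSim,
                                seed = seeds["schedSim"])
  recSim <- simulateRestRecording(layout, scheduleDuration(schedSim, 7),
                                  sa, config$age, seed = seeds["recSim"])
  recSim <- addTaskEvokedSA(recSim, schedSim, sa, seed = seeds["saSim"])
  dsSim <- .preprocessDataset(recSim, schedSim, "SIM", config$hbrFraction)

  schedReal <- makeSessionSchedule(nTrialsEach = config$nTrialsReal,
                                   seed = seeds["schedReal"])
  recReal <- simulateRestRecording(layout, scheduleDuration(schedReal, 7),
                                   sa, config$age, seed = seeds["recReal"])
  recReal <- addTaskEvokedSA(recReal, schedReal, sa, seed = seeds["saReal"])
  dsReal <- .preprocessDataset(recReal, schedReal,
                               c("ME_LEFT", "ME_RIGHT", "MI"),
                               config$hbrFraction)

  datasets <- list(
    SIM = list(hemo = dsSim$hemo, schedule = schedSim, mode = "SIM",
               tasks = "SIM"),
    REAL = list(hemo = dsReal$hemo, schedule = schedReal, mode = "REAL",
                tasks = c("ME_LEFT", "ME_RIGHT", "MI")))

  betas <- list(); glmCount <- 0L
  corrections <- list(); taskFits <- list()
  for (dsName in names(datasets)) {
    ds <- datasets[[dsName]]
    corrections[[dsName]] <- .allCorrections(ds$hemo, layout,
                                             config$solver,
                                             config$maxAROrder)
    for (m in .METHODS) {
      fit <- taskGLM(corrected(corrections[[dsName]][[m]]), ds$schedule,
                     mode = ds$mode, solver = config$solver,
                     maxAROrder = config$maxAROrder)
      glmCount <- glmCount + 1L
      taskFits[[dsName]][[m]] <- fit
      b <- fit@betas
      b$method <- m; b$dataset <- dsName; b$subject <- subject
      betas[[length(betas) + 1L]] <- b
    }
  }

  # channel selection from the GLM ALL task fit, per task and species
  selections <- list()
  for (task in .TASKS) {
    dsName <- if (task == "SIM") "SIM" else "REAL"
    for (sp in .SPECIES) {
      chSel <- selectBestChannel(taskFits[[dsName]]$GLM_ALL, task, layout,
                                 sp)
      selections[[length(selections) + 1L]] <- data.frame(
        subject = subject, task = task, species = sp, channel = chSel)
    }
  }
  selections <- do.call(rbind, selections)

  # single-trial metrics at the selected channels and subject-level
  # correlation matrices
  metrics <- list(); corMats <- list()
  for (task in .TASKS) {
    dsName <- if (task == "SIM") "SIM" else "REAL"
    ds <- datasets[[dsName]]
    epochsByMethod <- lapply(corrections[[dsName]], function(cr)
      epochAndBaseline(corrected(cr), ds$schedule, label = task))
    nosacEpochs <- epochsByMethod$NO_SAC
    for (m in .METHODS) {
      ep <- epochsByMethod[[m]]
      for (sp in .SPECIES) {
        chSel <- selections$channel[selections$task == task &
                                      selections$species == sp]
        row <- .rowOfChannel(ds$hemo, chSel, "regular")
        tm <- trialMetrics(ep, row, sp)
        metrics[[length(metrics) + 1L]] <- data.frame(
          subject = subject, task = task, species = sp, method = m,
          channel = chSel, trial = rep(tm$trial, 3),
          metric = rep(c("srmse", "cor_fisher_z", "cnr"), each = nrow(tm)),
          value = c(tm$srmse, tm$cor_fisher_z, tm$cnr))
        corMats[[paste(m, sp, task, sep = ".")]] <-
          sdcCorMat(ep, nosacEpochs, layout, sp)
      }
    }
  }
  list(betas = do.call(rbind, betas),
       metrics = do.call(rbind, metrics),
       selections = selections, corMats = corMats,
       glmCount = glmCount,
       pruned = list(SIM = dsSim$quality, REAL = dsReal$quality))
}

#' Run the full synthetic method comparison
#'
#' Simulates a cohort, preprocesses every subject's SIM and multi-task
#' sessions, applies all six correction variants, fits the task GLMs,
#' selects channels, computes the single-trial quality metrics, the group
#' channel-SDC correlation matrices with their pairwise Bayes-factor
#' tests, and the group beta maps: 6 methods x 2 species x 4 tasks = 48
#' correlation matrices and 48 beta maps, 15 method pairs x 4 tasks x 2
#' species = 120 tests, 12 task GLMs and 8 selected channels per subject.
#' Fully reproducible from the configuration and its master seed.
#'
#' @param config a list from [reportConfig].
#' @return a [ReportBundle-class].
#' @export
runFullComparison <- function(config = reportConfig()) {
  layout <- makeProbeLayout()
  seedNames <- c("schedSim", "recSim", "saSim", "schedReal", "recReal",
                 "saReal")
  subjectSeeds <- withr::with_seed(config$seed, {
    matrix(sample.int(.Machine$integer.max - 1L,
                      config$nSubjects * length(seedNames)),
           nrow = config$nSubjects,
           dimnames = list(NULL, seedNames))
  })
  perSubject <- lapply(seq_len(config$nSubjects), function(i)
    .processSubject(i, layout, config, subjectSeeds[i, ]))

  metrics <- do.call(rbind, lapply(perSubject, `[[`, "metrics"))
  rownames(metrics) <- NULL
  selections <- do.call(rbind, lapply(perSubject, `[[`, "selections"))
  betas <- do.call(rbind, lapply(perSubject, `[[`, "betas"))

  # group correlation matrices and their pairwise tests
  corMats <- list(); tests <- list()
  for (task in .TASKS) for (sp in .SPECIES) {
    cell <- lapply(.METHODS, function(m) {
      key <- paste(m, sp, task, sep = ".")
      averageCorMats(lapply(perSubject, function(ps) ps$corMats[[key]]))
    })
    names(cell) <- .METHODS
    for (m in .METHODS) corMats[[paste(m, sp, task, sep = ".")]] <- cell[[m]]
    tests[[paste(sp, task, sep = ".")]] <-
      compareCorMats(cell, task = task, species = sp)
  }
  corMatTests <- do.call(rbind, tests)
  rownames(corMatTests) <- NULL

  # group beta maps: per method, task and species
  betaMaps <- list()
  for (m in .METHODS) for (task in .TASKS) for (sp in .SPECIES) {
    dsName <- if (task == "SIM") "SIM" else "REAL"
    bySubject <- lapply(perSubject, function(ps) {
      b <- ps$betas
      b[b$method == m & b$dataset == dsName, ]
    })
    betaMaps[[paste(m, sp, task, sep = ".")]] <-
      betaMap(bySubject, task, sp)
  }

  new("ReportBundle", metrics = metrics, corMats = corMats,
      corMatTests = corMatTests, betaMaps = betaMaps,
      selections = selections, config = config,
      seeds = list(master = config$seed, subjects = subjectSeeds,
                   glmsPerSubject = perSubject[[1]]$glmCount))
}

#' Subject-level metric summary of a report bundle
#'
#' Averages single-trial metric values across trials per subject, channel
#' and method, and merges ME_LEFT and ME_RIGHT into a single ME value per
#' subject (computed separately, then averaged).
#'
#' @param bundle a [ReportBundle-class].
#' @param mergeME merge the two motor-execution tasks into "ME".
#' @return data.frame: subject, task, species, method, metric, value.
#' @export
summariseMetrics <- function(bundle, mergeME = TRUE) {
  m <- bundle@metrics
  agg <- stats::aggregate(value ~ subject + task + species + method + metric,
                          data = m, FUN = mean, na.rm = TRUE,
                          na.action = stats::na.pass)
  if (mergeME) {
    me <- agg[agg$task %in% c("ME_LEFT", "ME_RIGHT"), ]
    if (nrow(me)) {
      me <- stats::aggregate(value ~ subject + species + method + metric,
                             data = me, FUN = mean, na.rm = TRUE,
                             na.action = stats::na.pass)
      me$task <- "ME"
      agg <- rbind(agg[!(agg$task %in% c("ME_LEFT", "ME_RIGHT")), ],
                   me[names(agg)])
    }
  }
  agg[order(agg$metric, agg$task, agg$species, agg$method, agg$subject), ]
}
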