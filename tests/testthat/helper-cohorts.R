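# Shared cohort-derived fixtures, computed once per test run.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# default study-condition cohort (planted modules, hubs, group effects)
defaultCohort <- function() {
  fixture("defaultCohort", function() generateCohort(cohortSpec(), seed = 101))
}

subjectFCs <- function(cohort) {
  lapply(seq_len(nSubjects(cohort)),
         function(i) computeFC(subjectTimeseries(cohort, i)))
}

# group-mean FC matrices of the default cohort
defaultGroupFC <- function() {
  fixture("defaultGroupFC", function() {
    coh <- defaultCohort()
    fcs <- subjectFCs(coh)
    split(fcs, cohortMetadata(coh)$group) |> lapply(groupMeanNetwork)
  })
}

# strongly modular cohort used for community-recovery checks
modularCohort <- function() {
  fixture("modularCohort", function() {
    generateCohort(cohortSpec(rhoIn = 0.6, rhoOut = 0.1), seed = 103)
  })
}

modularGroupFC <- function() {
  fixture("modularGroupFC", function() {
    coh <- modularCohort()
    fcs <- subjectFCs(coh)
    split(fcs, cohortMetadata(coh)$group) |> lapply(groupMeanNetwork)
  })
}

# default-cohort feature table at the reference sparsity (light SW nulls)
defaultFeatureTable <- function() {
  fixture("defaultFeatureTable", function() {
    buildFeatureTable(defaultCohort(), 0.16, nRandomSW = 10L, seed = 7)
  })
}

# small cheap spec for calibration loops
smallSpec <- function(...) {
  cohortSpec(nPerGroup = 15L, nRois = 20L, nTimepoints = 60L, nModules = 4L,
             ...)
}
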