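# Synthetic cohorts with closed-form FTV(PEt, SERt) per patient.
#
# Each patient's tumor is a mixture of volume compartments with
# truncated-normal (PE, SER) kinetics.  FTV at a threshold pair is the sum
# over compartments of (volume at that timepoint) x P(PE >= PEt) x
# P(SER >= SERt), so the full 198-cell grid evaluates in closed form.
# Discrimination between pCR and non-pCR is carried by "informative"
# compartments whose shrinkage depends on outcome; "random" compartments
# shrink with outcome-independent noise and "none" compartments (background
# parenchymal enhancement) do not shrink.  Thresholds that isolate the
# informative compartment therefore maximize the AUC: the planted optimum.

cohortCompartment <- function(label, type, volMeanlog, volSdlog,
                              peMu, peMuSd, peSd, serMu, serMuSd, serSd) {
  stopifnot(type %in% c("informative", "random", "none"))
  list(label = label, type = type,
       volMeanlog = volMeanlog, volSdlog = volSdlog,
       peMu = peMu, peMuSd = peMuSd, peSd = peSd,
       serMu = serMu, serMuSd = serMuSd, serSd = serSd)
}

subtypeTemplates <- function() {
  list(
    # HR+/HER2-: high background parenchymal enhancement and a low-PE rim
    # dilute the change signal unless PEt is raised; planted optimum at
    # high PEt, any SERt.
    "HR+/HER2-" = list(
      compartments = list(
        cohortCompartment("tumor", "informative", log(30), 0.5,
                          peMu = 180, peMuSd = 15, peSd = 35,
                          serMu = 1.1, serMuSd = 0.10, serSd = 0.30),
        cohortCompartment("rim", "random", log(15), 0.9,
                          peMu = 75, peMuSd = 10, peSd = 25,
                          serMu = 1.5, serMuSd = 0.15, serSd = 0.50),
        cohortCompartment("bpe", "none", log(20), 0.7,
                          peMu = 85, peMuSd = 8, peSd = 20,
                          serMu = 0.55, serMuSd = 0.05, serSd = 0.15)),
      planted = list(pe = c(120, 200), ser = c(0, 2),
                     pair = c(160, 1.0))),
    # HER2+: the outcome signal sits in a high-SER washout compartment;
    # a same-PE plateau compartment shrinks at random, so only a high SERt
    # isolates the signal.
    "HER2+" = list(
      compartments = list(
        cohortCompartment("washout", "informative", log(20), 0.5,
                          peMu = 160, peMuSd = 15, peSd = 35,
                          serMu = 1.7, serMuSd = 0.08, serSd = 0.25),
        cohortCompartment("plateau", "random", log(20), 0.8,
                          peMu = 160, peMuSd = 15, peSd = 35,
                          serMu = 0.9, serMuSd = 0.08, serSd = 0.25)),
      planted = list(pe = c(30, 200), ser = c(1.2, 2),
                     pair = c(120, 1.6))),
    # TNBC: a low-PE nuisance compartment with wide SER forces PEt up;
    # SERt is uninformative.
    "TNBC" = list(
      compartments = list(
        cohortCompartment("tumor", "informative", log(25), 0.5,
                          peMu = 170, peMuSd = 15, peSd = 35,
                          serMu = 1.5, serMuSd = 0.10, serSd = 0.30),
        cohortCompartment("nuisance", "random", log(15), 0.9,
                          peMu = 75, peMuSd = 10, peSd = 25,
                          serMu = 1.2, serMuSd = 0.20, serSd = 0.50)),
      planted = list(pe = c(100, 200), ser = c(0, 2),
                     pair = c(150, 1.0))))
}

#' Specification of a synthetic cohort
#'
#' Cohort sizes and pCR rates default to the neoadjuvant trial structure
#' the generator emulates: 45 HR+/HER2- (pCR rate 6/45), 39 HER2+ (16/39)
#' and 30 triple-negative (11/30) patients.  The outcome-dependent
#' shrinkage model and the subtype compartment mixtures (with their
#' planted optimal threshold regions) have fixed defaults; see the
#' package vignette for the rationale behind each value.
#'
#' @param nPerSubtype named integer vector of patients per subtype.
#' @param pcrRate named vector of pCR probabilities per subtype.
#' @param shrinkage list: `pcr` and `nonpcr` residual volume fractions at
#'   timepoints 1..4 for informative compartments, `sdlogInformative`
#'   patient-level lognormal noise, `randomResidual` and `sdlogRandom`
#'   for outcome-independent compartments.
#' @param templates subtype compartment templates (advanced use).
#' @param nMissingHer2 extra patients with missing HER2 status (in the
#'   full cohort but no subtype group).
#' @param seed integer RNG seed.
#' @return A list of class "SyntheticCohortSpec".
#' @export
syntheticCohortSpec <- function(
    nPerSubtype = c("HR+/HER2-" = 45L, "HER2+" = 39L, "TNBC" = 30L),
    pcrRate = c("HR+/HER2-" = 6 / 45, "HER2+" = 16 / 39, "TNBC" = 11 / 30),
    shrinkage = list(pcr = c(1, 0.35, 0.05, 0.01),
                     nonpcr = c(1, 0.75, 0.30, 0.15),
                     sdlogInformative = 0.8,
                     randomResidual = c(1, 0.80, 0.60, 0.50),
                     sdlogRandom = 0.9),
    templates = subtypeTemplates(),
    nMissingHer2 = 0L,
    seed = 1L) {
  stopifnot(length(nPerSubtype) >= 1, all(nPerSubtype > 0),
            all(names(nPerSubtype) %in% names(templates)),
            all(names(nPerSubtype) %in% names(pcrRate)),
            all(pcrRate >= 0 & pcrRate <= 1),
            length(shrinkage$pcr) == 4, length(shrinkage$nonpcr) == 4,
            nMissingHer2 >= 0L)
  structure(list(nPerSubtype = nPerSubtype, pcrRate = pcrRate,
                 shrinkage = shrinkage, templates = templates,
                 nMissingHer2 = as.integer(nMissingHer2),
                 seed = as.integer(seed)),
            class = "SyntheticCohortSpec")
}

#' Generate a synthetic FTV cohort
#'
#' Draws per-patient outcomes, compartment volumes, kinetics and shrinkage
#' trajectories and evaluates FTV over the full threshold grid at all four
#' MRI timepoints in closed form.  Bit-reproducible given (spec, seed).
#'
#' @param spec a [syntheticCohortSpec()].
#' @param grid threshold grid data.frame from [thresholdGrid()].
#' @return An [FtvCohort-class]; the generating parameters (including the
#'   planted per-subtype optimal threshold regions) are available via
#'   [groundTruth()].
#' @examples
#' coh <- generateCohort(syntheticCohortSpec(seed = 7))
#' coh
#' @export
generateCohort <- function(spec, grid = thresholdGrid()) {
  stopifnot(inherits(spec, "SyntheticCohortSpec"))
  pe <- unique(grid$pe_t)
  ser <- unique(grid$ser_t)
  cellIndex <- function(M) as.vector(t(M))  # [pe, ser] -> grid row order
  withSeed(spec$seed, {
    ids <- character(0); hr <- character(0); her2 <- character(0)
    subtype <- character(0); pcr <- logical(0)
    ftv <- lapply(1:4, function(i) NULL)
    patientParams <- list()
    addPatient <- function(id, hrv, her2v, sub, template, isPcr) {
      sh <- spec$shrinkage
      base <- if (isPcr) sh$pcr else sh$nonpcr
      cells <- matrix(0, nrow(grid), 4)
      params <- list()
      for (comp in template$compartments) {
        v0 <- exp(rnorm(1, comp$volMeanlog, comp$volSdlog))
        peMu <- rtruncnorm0(1, comp$peMu, comp$peMuSd)
        serMu <- rtruncnorm0(1, comp$serMu, comp$serMuSd)
        res <- switch(comp$type,
          informative = c(1, base[2:4] *
                            exp(rnorm(3, 0, sh$sdlogInformative))),
          random = c(1, sh$randomResidual[2:4] *
                       exp(rnorm(3, 0, sh$sdlogRandom))),
          none = rep(1, 4))
        tails <- outer(truncnormTail(pe, peMu, comp$peSd),
                       truncnormTail(ser, serMu, comp$serSd))
        cellTails <- cellIndex(tails)
        for (tp in 1:4)
          cells[, tp] <- cells[, tp] + v0 * res[tp] * cellTails
        params[[comp$label]] <- list(v0 = v0, peMu = peMu, serMu = serMu,
                                     residuals = res, type = comp$type)
      }
      ids <<- c(ids, id); hr <<- c(hr, hrv); her2 <<- c(her2, her2v)
      subtype <<- c(subtype, sub); pcr <<- c(pcr, isPcr)
      for (tp in 1:4) ftv[[tp]] <<- cbind(ftv[[tp]], cells[, tp])
      patientParams[[id]] <<- params
    }
    for (sub in names(spec$nPerSubtype)) {
      n <- spec$nPerSubtype[[sub]]
      template <- spec$templates[[sub]]
      flags <- rbinom(n, 1, spec$pcrRate[[sub]]) == 1
      for (i in seq_len(n)) {
        hrv <- switch(sub, "HR+/HER2-" = "+", "TNBC" = "-",
                      sample(c("+", "-"), 1))
        her2v <- if (sub == "HER2+") "+" else "-"
        addPatient(sprintf("%s_%03d", gsub("[^A-Za-z0-9]", "", sub), i),
                   hrv, her2v, sub, template, flags[i])
      }
    }
    if (spec$nMissingHer2 > 0) {
      template <- spec$templates[[1]]
      rate <- mean(spec$pcrRate[names(spec$nPerSubtype)])
      for (i in seq_len(spec$nMissingHer2))
        addPatient(sprintf("MISS_%03d", i), "+", NA_character_,
                   NA_character_, template, rbinom(1, 1, rate) == 1)
    }
    assays <- stats::setNames(
      lapply(1:4, function(tp) {
        m <- ftv[[tp]]
        dimnames(m) <- list(NULL, ids)
        m
      }),
      paste0("ftv", 1:4))
    planted <- lapply(spec$templates[names(spec$nPerSubtype)],
                      `[[`, "planted")
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = assays,
      rowData = S4Vectors::DataFrame(grid),
      colData = S4Vectors::DataFrame(
        patient_id = ids, hr = hr, her2 = her2,
        subtype = subtype, pcr = pcr, row.names = ids),
      metadata = list(groundTruth = list(
        spec = spec, planted = planted, patients = patientParams)))
    new("FtvCohort", se)
  })
}

#' Derive the subtype label from receptor status
#'
#' HER2+ regardless of HR; triple-negative when both receptors are
#' negative; HR+/HER2- otherwise.  Missing HER2 gives NA (the patient
#' belongs to the full cohort but no subtype group).
#'
#' @param hr,her2 character vectors of "+" / "-" (HER2 may be NA).
#' @return character vector of subtype labels.
#' @export
deriveSubtype <- function(hr, her2) {
  ifelse(is.na(her2), NA_character_,
         ifelse(her2 == "+", "HER2+",
                ifelse(hr == "-", "TNBC", "HR+/HER2-")))
}

#' Accessors for FtvCohort objects
#'
#' @param cohort an [FtvCohort-class].
#' @return `pcrStatus`: logical vector; `subtypes`: character vector;
#'   `peThresholds`/`serThresholds`: the grid levels; `groundTruth`: the
#'   generator's ground-truth list (NULL for cohorts read from files).
#' @export
pcrStatus <- function(cohort) SummarizedExperiment::colData(cohort)$pcr

#' @rdname pcrStatus
#' @export
subtypes <- function(cohort) SummarizedExperiment::colData(cohort)$subtype

#' @rdname pcrStatus
#' @export
peThresholds <- function(cohort)
  unique(SummarizedExperiment::rowData(cohort)$pe_t)

#' @rdname pcrStatus
#' @export
serThresholds <- function(cohort)
  unique(SummarizedExperiment::rowData(cohort)$ser_t)

#' @rdname pcrStatus
#' @export
groundTruth <- function(cohort) S4Vectors::metadata(cohort)$groundTruth

#' Predictor matrix over the grid
#'
#' Returns the (grid cells x patients) matrix of one FTV-derived predictor:
#' absolute FTV at a timepoint ("ftv1".."ftv4") or percent change from
#' baseline ("dftv2".."dftv4").  Percent change is NA for patients with
#' zero baseline FTV at that cell (excluded cell-wise from analyses).
#'
#' @param cohort an [FtvCohort-class].
#' @param predictor predictor name.
#' @return numeric matrix.
#' @export
predictorMatrix <- function(cohort,
                            predictor = c("ftv1", "ftv2", "ftv3", "ftv4",
                                          "dftv2", "dftv3", "dftv4")) {
  predictor <- match.arg(predictor)
  if (startsWith(predictor, "ftv"))
    return(SummarizedExperiment::assay(cohort, predictor))
  tp <- sub("dftv", "ftv", predictor)
  f1 <- SummarizedExperiment::assay(cohort, "ftv1")
  fn <- SummarizedExperiment::assay(cohort, tp)
  out <- 100 * (fn - f1) / f1
  out[f1 == 0] <- NA_real_
  out
}

#' Write / read cohort FTV tables as CSV
#'
#' The interchange format for cohort tables: one row per patient with
#' columns patient_id, hr, her2, subtype, pcr and ftv_1..ftv_4 evaluated
#' at one threshold pair.
#'
#' @param cohort an [FtvCohort-class].
#' @param path CSV path.
#' @param pe_t,ser_t the threshold pair to tabulate.
#' @return `readCohortCsv` returns a data.frame.
#' @export
writeCohortCsv <- function(cohort, path, pe_t = 70, ser_t = 0) {
  rd <- SummarizedExperiment::rowData(cohort)
  i <- which(rd$pe_t == pe_t & rd$ser_t == ser_t)
  if (length(i) != 1L)
    stop(sprintf("threshold pair (%g, %g) is not on the cohort grid",
                 pe_t, ser_t))
  cd <- as.data.frame(SummarizedExperiment::colData(cohort))
  out <- data.frame(patient_id = cd$patient_id, hr = cd$hr, her2 = cd$her2,
                    subtype = cd$subtype, pcr = cd$pcr)
  for (tp in 1:4)
    out[[paste0("ftv_", tp)]] <-
      SummarizedExperiment::assay(cohort, paste0("ftv", tp))[i, ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortCsv
#' @export
readCohortCsv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "pcr", paste0("ftv_", 1:4))
  if (!all(need %in% names(x)))
    stop("cohort CSV must contain columns: ", paste(need, collapse = ", "))
  x$pcr <- as.logical(x$pcr)
  x
}

#' Assemble an FtvCohort from a long FTV table
#'
#' Builds the grid-by-patient container from the imaging stage's long
#' output (patient_id, timepoint, pe_t, ser_t, ftv_cc) joined with a
#' clinical table (patient_id, hr, her2, pcr).  Missing patient/timepoint
#' combinations become NA.
#'
#' @param ftvTable long data.frame from [runImagingStage()].
#' @param clinical data.frame with patient_id, hr, her2, pcr.
#' @return An [FtvCohort-class].
#' @export
ftvCohortFromTable <- function(ftvTable, clinical) {
  need <- c("patient_id", "timepoint", "pe_t", "ser_t", "ftv_cc")
  stopifnot(all(need %in% names(ftvTable)),
            all(c("patient_id", "hr", "her2", "pcr") %in% names(clinical)))
  grid <- unique(ftvTable[order(ftvTable$pe_t, ftvTable$ser_t),
                          c("pe_t", "ser_t")])
  rownames(grid) <- NULL
  ids <- clinical$patient_id
  cellKey <- function(p, s) paste(p, s, sep = "/")
  rowOf <- stats::setNames(seq_len(nrow(grid)),
                           cellKey(grid$pe_t, grid$ser_t))
  assays <- stats::setNames(lapply(1:4, function(tp) {
    m <- matrix(NA_real_, nrow(grid), length(ids),
                dimnames = list(NULL, ids))
    sub <- ftvTable[ftvTable$timepoint == tp, ]
    if (nrow(sub))
      m[cbind(rowOf[cellKey(sub$pe_t, sub$ser_t)],
              match(sub$patient_id, ids))] <- sub$ftv_cc
    m
  }), paste0("ftv", 1:4))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays,
    rowData = S4Vectors::DataFrame(grid),
    colData = S4Vectors::DataFrame(
      patient_id = ids, hr = clinical$hr, her2 = clinical$her2,
      subtype = deriveSubtype(clinical$hr, clinical$her2),
      pcr = as.logical(clinical$pcr), row.names = ids))
  new("FtvCohort", se)
}
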