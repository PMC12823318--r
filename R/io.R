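#' Load the packaged population model and residual-error specification
#'
#' Reads the published final population estimates shipped with the package
#' (`inst/extdata/salmeterol_poppk.yaml`) or a user configuration with the
#' same schema. A light checksum against embedded reference values guards
#' the packaged file against silent corruption.
#'
#' @param path Optional path to a YAML configuration; default is the
#'   packaged file.
#' @return For `load_population_config()`, a list with elements `pop`
#'   (a [population_model()]) and `ruv` (a [ruv_spec()]).
#'   `default_population_model()` and `default_ruv_spec()` are shorthands
#'   for the two elements.
#' @examples
#' pop <- default_population_model()
#' pop$typicals$cls_f # 193 L/h
#' @export
load_population_config <- function(path = NULL) {
  packaged <- is.null(path)
  if (packaged) {
    path <- system.file("extdata", "salmeterol_poppk.yaml", package = "salmpk")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  need <- c("typicals", "covariates", "iiv_cv_percent", "ruv")
  missing <- setdiff(need, names(cfg))
  if (length(missing)) {
    stop("configuration lacks section(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  typ <- do.call(structural_params, cfg$typicals)
  if (packaged &&
    !(isTRUE(all.equal(typ$cls_f, 193)) &&
      isTRUE(all.equal(typ$k14, 0.00094)) &&
      isTRUE(all.equal(typ$ur_prod, 0.079)) &&
      isTRUE(all.equal(cfg$covariates$theta_k14_athlete, 2.91)))) {
    stop("packaged configuration failed its checksum against embedded values", call. = FALSE)
  }
  pop <- population_model(
    typicals = typ,
    theta_cls_athlete = cfg$covariates$theta_cls_athlete,
    theta_k14_athlete = cfg$covariates$theta_k14_athlete,
    omega_cv = unlist(cfg$iiv_cv_percent),
    ur_prod_iiv_usg_uncorrected_only =
      isTRUE(cfg$ur_prod_iiv_usg_uncorrected_only)
  )
  ruv <- ruv_spec(
    cv = unlist(cfg$ruv$cv),
    corr_plasma = cfg$ruv$corr_plasma %||% 0,
    corr_urine = cfg$ruv$corr_urine %||% 0
  )
  list(pop = pop, ruv = ruv)
}

#' @rdname load_population_config
#' @export
default_population_model <- function() load_population_config()$pop

#' @rdname load_population_config
#' @export
default_ruv_spec <- function() load_population_config()$ruv

# event-record dataset dialect -----------------------------------------------

.cmt_table <- tibble::tibble(
  CMT = c(1L, 3L, 4L, 5L),
  matrix = c("plasma", "plasma", "urine", "urine"),
  compound = c(
    "salmeterol", "alpha-hydroxysalmeterol",
    "salmeterol", "alpha-hydroxysalmeterol"
  )
)

.mandatory_cols <- c("ID", "TIME", "EVID", "AMT", "DV", "CMT", "MDV", "LLOQ")

#' Read a rectangular pharmacometric event-record dataset
#'
#' The on-disk dialect is a plain CSV with one row per dose or observation:
#' `ID`; `TIME` (h, absolute); `EVID` (0 observation, 1 dose); `AMT` (nmol,
#' dose rows); `DV` (ng/mL as recorded by the assay); `CMT` (1 plasma
#' salmeterol, 3 plasma metabolite, 4 urine salmeterol, 5 urine
#' metabolite); `MDV`; `LLOQ` (ng/mL); optional `USG`, `UINT_START` (urine
#' collection start, h; mandatory on urine observation rows), `UVOL`
#' (recorded collection volume, L), `STUDY`, `TYPE`
#' (athlete/healthy/asthmatic), `DEVICE`, `RUVGRP` (low/mid/high), `CORR`
#' (parent-metabolite errors correlated in this study, 0/1).
#'
#' On load, concentrations with a recorded USG are standardized via
#' [usg_correct()] (the raw value is kept in `DV_RAW`), and molar
#' equivalents are stored in `DV_NMOL` / `LLOQ_NMOL`.
#'
#' @param path CSV file path.
#' @return A validated tibble with the derived columns above plus
#'   `matrix`/`compound` decoded from `CMT`.
#' @export
read_pk_dataset <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_pk_dataset(tibble::as_tibble(raw))
}

#' @rdname read_pk_dataset
#' @param records An in-memory event-record tibble to validate/normalize.
#' @export
validate_pk_dataset <- function(records) {
  records <- tibble::as_tibble(records)
  missing <- setdiff(.mandatory_cols, names(records))
  if (length(missing)) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  for (opt in c("USG", "UINT_START", "UVOL")) {
    if (!opt %in% names(records)) records[[opt]] <- NA_real_
  }
  if (!"STUDY" %in% names(records)) records$STUDY <- "study_1"
  if (!"TYPE" %in% names(records)) records$TYPE <- "healthy"
  if (!"RUVGRP" %in% names(records)) records$RUVGRP <- NA_character_
  if (!"CORR" %in% names(records)) records$CORR <- 0L
  if (any(records$TIME < 0)) stop("negative TIME", call. = FALSE)
  if (!all(records$EVID %in% c(0L, 1L))) stop("EVID must be 0 or 1", call. = FALSE)
  if (!all(records$CMT %in% .cmt_table$CMT)) {
    stop("CMT must be one of 1, 3, 4, 5", call. = FALSE)
  }
  dose <- records$EVID == 1L
  if (any(dose & (is.na(records$AMT) | records$AMT <= 0))) {
    stop("dose rows must have AMT > 0", call. = FALSE)
  }
  if (any(dose & records$MDV != 1L)) {
    stop("dose rows must have MDV = 1", call. = FALSE)
  }
  urine_obs <- !dose & records$CMT %in% c(4L, 5L)
  if (any(urine_obs & is.na(records$UINT_START))) {
    stop("urine observation rows must carry UINT_START", call. = FALSE)
  }
  if (any(urine_obs & records$UINT_START > records$TIME)) {
    stop("UINT_START must be <= TIME", call. = FALSE)
  }
  dec <- .cmt_table[match(records$CMT, .cmt_table$CMT), c("matrix", "compound")]
  records$matrix <- dec$matrix
  records$compound <- dec$compound
  records$DV_RAW <- records$DV
  obs <- !dose & !is.na(records$DV)
  records$DV[obs] <- usg_correct(records$DV_RAW[obs], records$USG[obs])
  records$DV_NMOL <- NA_real_
  records$DV_NMOL[obs] <- ifelse(
    records$compound[obs] == "salmeterol",
    conc_to_nmol_per_l(records$DV[obs], "salmeterol"),
    conc_to_nmol_per_l(records$DV[obs], "alpha-hydroxysalmeterol")
  )
  records$LLOQ_NMOL <- ifelse(
    records$compound == "salmeterol",
    records$LLOQ / .MW_SALM * 1000,
    records$LLOQ / .MW_AOH * 1000
  )
  records
}

#' Write an event-record dataset to CSV
#'
#' Only the on-disk dialect columns are written; derived columns
#' (`DV_RAW`, `DV_NMOL`, ...) are dropped so that a write/read round trip
#' is lossless on the assay-native scale.
#'
#' @param records Event-record tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_pk_dataset <- function(records, path) {
  cols <- intersect(
    c(
      .mandatory_cols, "USG", "UINT_START", "UVOL",
      "STUDY", "TYPE", "DEVICE", "RUVGRP", "CORR"
    ),
    names(records)
  )
  utils::write.csv(records[, cols], path, row.names = FALSE, na = "")
  invisible(path)
}
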