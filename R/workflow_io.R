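#' Long-format study dataset dialect
#'
#' Datasets use the NONMEM-convention long format: one row per dose event
#' or observation, columns `ID`, `TIME` (h), `AMT` (mg; dose rows only),
#' `DV` (mg/L for concentrations, mm^3 for tumor volumes; observation rows
#' only), `EVID` (1 dose, 0 observation), `MDV` (1 when `DV` is missing),
#' `CMT` (1 central, 2 tumor), `WT` (kg), `DOSEGRP` (nominal dose label,
#' mg/kg) and `BLQ` (1 for a below-quantification-limit observation imputed
#' at half the limit).  On disk the missing marker is `"."`.
#'
#' `read_dataset()` validates structure and reports offending row numbers;
#' `write_dataset()` writes the same dialect losslessly.
#'
#' @param path CSV file path.
#' @return `read_dataset()`: a validated data frame; `write_dataset()`:
#'   `path`, invisibly.
#' @export
read_dataset <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c(".", "NA", ""))
  validate_dataset(d)
}

#' @rdname read_dataset
#' @param data A dataset data frame.
#' @export
write_dataset <- function(data, path) {
  d <- validate_dataset(data)
  for (nm in names(d)) d[[nm]] <- ifelse(is.na(d[[nm]]), ".", as.character(d[[nm]]))
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_dataset
#' @param lloq An [lloq_rule()] used to check that below-limit rows carry
#'   the imputed half-limit value (warning otherwise), or `NULL` to skip.
#' @export
validate_dataset <- function(data, lloq = lloq_rule()) {
  need <- c("ID", "TIME", "AMT", "DV", "EVID", "MDV", "CMT", "WT",
            "DOSEGRP", "BLQ")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("dataset is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  d <- data[, need]
  for (nm in need) d[[nm]] <- as.numeric(d[[nm]])
  bad_num <- which(vapply(seq_len(nrow(d)), function(i) {
    any(is.na(d[i, c("ID", "TIME", "EVID", "MDV")]))
  }, logical(1)))
  if (length(bad_num)) {
    stop("malformed row(s) (non-numeric or missing ID/TIME/EVID/MDV): ",
         paste(utils::head(bad_num, 5), collapse = ", "))
  }
  is_dose <- d$EVID == 1
  bad <- which(is_dose & (is.na(d$AMT) | d$AMT <= 0 | !is.na(d$DV)))
  if (length(bad)) {
    stop("dose row(s) must have AMT > 0 and missing DV: row ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  bad <- which(!is_dose & d$MDV == 0 & is.na(d$DV))
  if (length(bad)) {
    stop("observation row(s) with MDV = 0 must carry DV: row ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  if (!is.null(lloq)) {
    odd <- which(!is_dose & d$BLQ %in% 1 &
                   abs(d$DV - lloq$first_blq_value) > 1e-9)
    if (length(odd)) {
      warning("below-limit row(s) not imputed at LLOQ/2 = ",
              lloq$first_blq_value, ": row ",
              paste(utils::head(odd, 5), collapse = ", "))
    }
  }
  d
}

# split a PK dataset into the per-subject pieces the likelihood needs
.split_subjects <- function(data) {
  lapply(split(data, data$ID), function(s) {
    s <- s[order(s$TIME, -s$EVID), , drop = FALSE]
    obs <- s[s$EVID == 0 & s$MDV == 0, , drop = FALSE]
    list(id = s$ID[1L],
         wt = s$WT[1L],
         dose_times = s$TIME[s$EVID == 1],
         dose_amounts = s$AMT[s$EVID == 1],
         obs_times = obs$TIME,
         dv = obs$DV,
         blq = obs$BLQ %in% 1,
         dosegrp = s$DOSEGRP[1L])
  })
}
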