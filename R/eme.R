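#' Fatty-acid profile constructor
#'
#' Bundles the six informative milk fatty acids (g / 100 g total fatty acids)
#' that enter the enteric-methane prediction equations: butyric acid (C4:0),
#' iso-palmitic acid (C16:0 iso), iso-oleic acid (C18:1 trans-10), vaccenic
#' acid (C18:1 trans-11), oleic acid (C18:1 cis-9) and linoleic acid
#' (C18:2 cis-9,cis-12). The two trans C18:1 isomers are stored separately
#' (gas chromatography distinguishes them) and summed at evaluation time,
#' since the prediction equations use their sum under a shared coefficient.
#'
#' All arguments are vectorised; they are recycled to a common length.
#'
#' @param c4_0,c16_0iso,c18_1_t10,c18_1_t11,c18_1_c9,c18_2_c9c12 numeric,
#'   g/100 g of total fatty acids, each in \[0, 100\].
#' @return a data.frame of class `fa_profile` with the six columns.
#' @export
fa_profile <- function(c4_0 = 0, c16_0iso = 0, c18_1_t10 = 0, c18_1_t11 = 0,
                       c18_1_c9 = 0, c18_2_c9c12 = 0) {
  fa <- data.frame(c4_0 = c4_0, c16_0iso = c16_0iso, c18_1_t10 = c18_1_t10,
                   c18_1_t11 = c18_1_t11, c18_1_c9 = c18_1_c9,
                   c18_2_c9c12 = c18_2_c9c12)
  validate_fa_profile(fa)
  class(fa) <- c("fa_profile", class(fa))
  fa
}

validate_fa_profile <- function(fa) {
  cols <- c("c4_0", "c16_0iso", "c18_1_t10", "c18_1_t11", "c18_1_c9",
            "c18_2_c9c12")
  missing <- setdiff(cols, names(fa))
  if (length(missing))
    stop("fatty-acid profile lacks column(s): ", paste(missing, collapse = ", "))
  m <- as.matrix(fa[cols])
  if (any(!is.finite(m))) stop("fatty-acid proportions must be finite")
  if (any(m < 0)) stop("fatty-acid proportions must be >= 0 g/100 g")
  if (any(m > 100)) stop("fatty-acid proportions must be <= 100 g/100 g")
  if (any(rowSums(m) > 100 + 1e-8))
    stop("the six fatty acids cannot exceed 100 g/100 g in total")
  invisible(fa)
}

#' Methane yield from the milk fatty-acid profile
#'
#' Evaluates the meta-analysis equation predicting enteric methane yield per
#' kg of dry-matter intake from four milk fatty-acid terms:
#' \deqn{CH4/DM = 23.39 + 9.74\,C16:0iso - 1.06\,(C18:1 t10 + t11)
#'   - 1.75\,C18:2 c9c12}
#' Negative outputs (possible for extreme inputs) are returned as-is with a
#' warning, never clipped.
#'
#' @param fa an [fa_profile()] (or data.frame with its columns).
#' @return numeric vector, g CH4 per kg dry-matter intake.
#' @export
methane_yield <- function(fa) {
  validate_fa_profile(fa)
  out <- 23.39 + 9.74 * fa$c16_0iso - 1.06 * (fa$c18_1_t10 + fa$c18_1_t11) -
    1.75 * fa$c18_2_c9c12
  if (any(out < 0))
    warning(sum(out < 0), " methane-yield value(s) below 0 g/kg retained unclipped")
  out
}

#' Methane intensity per kg of fat/protein-corrected milk
#'
#' Evaluates the companion meta-analysis equation:
#' \deqn{CH4/CM = 21.13 - 1.38\,C4:0 + 8.53\,C16:0iso - 0.22\,C18:1 c9
#'   - 0.59\,(C18:1 t10 + t11)}
#'
#' @inheritParams methane_yield
#' @return numeric vector, g CH4 per kg corrected milk.
#' @export
methane_intensity_milk <- function(fa) {
  validate_fa_profile(fa)
  out <- 21.13 - 1.38 * fa$c4_0 + 8.53 * fa$c16_0iso - 0.22 * fa$c18_1_c9 -
    0.59 * (fa$c18_1_t10 + fa$c18_1_t11)
  if (any(out < 0))
    warning(sum(out < 0), " methane-intensity value(s) below 0 g/kg retained unclipped")
  out
}

#' Fat/protein-corrected daily milk yield
#'
#' dCMY = dMY x CF with the correction factor
#' CF = 0.337 + 0.116 x fat\% + 0.06 x protein\%.
#'
#' @param dmy daily milk yield, kg/d (>= 0).
#' @param fat_pct,protein_pct milk fat and protein, \%.
#' @return corrected milk yield, kg/d.
#' @export
corrected_milk_yield <- function(dmy, fat_pct, protein_pct) {
  if (any(!is.finite(dmy)) || any(dmy < 0))
    stop("daily milk yield must be finite and >= 0 kg/d")
  cf <- 0.337 + 0.116 * fat_pct + 0.06 * protein_pct
  dmy * cf
}

#' Daily methane production
#'
#' dCH4 = CH4/CM x dCMY, i.e. intensity per kg corrected milk times the
#' corrected milk yield.
#'
#' @param ch4_cm methane intensity, g/kg corrected milk.
#' @param dcmy corrected milk yield, kg/d (>= 0).
#' @return g CH4 per day.
#' @export
daily_methane <- function(ch4_cm, dcmy) {
  if (any(!is.finite(dcmy)) || any(dcmy < 0))
    stop("corrected milk yield must be finite and >= 0 kg/d")
  ch4_cm * dcmy
}

#' Methane intensity per kg of cheese (fresh curd or solids)
#'
#' Quotient of daily methane by daily cheese yield. A non-positive cheese
#' yield makes the trait undefined; such records must be excluded upstream,
#' so here it is an error.
#'
#' @param dch4 daily methane, g/d.
#' @param dcy daily cheese yield (fresh curd or solids), kg/d, strictly > 0.
#' @return g CH4 per kg cheese.
#' @export
methane_intensity_cheese <- function(dch4, dcy) {
  if (any(!is.finite(dcy)) || any(dcy <= 0))
    stop("cheese-intensity trait undefined: daily cheese yield must be > 0 kg/d")
  dch4 / dcy
}

#' All enteric-methane phenotypes for a set of milk records
#'
#' Chains the five reference traits from a table of milk records:
#' methane yield (`ch4_dm`, g/kg DMI), methane intensity-milk (`ch4_cm`,
#' g/kg corrected milk), daily production (`dch4`, g/d) and the two cheese
#' intensities (`ch4_cy_curd`, `ch4_cy_solids`, g/kg), plus the auxiliary
#' yields `dcmy`, `dcy_curd`, `dcy_solids` (kg/d). Daily cheese yields are
#' dMY times the corresponding cheese-yield percentage.
#'
#' Records with non-positive cheese yields get `NA` for the cheese
#' intensities only (they stay usable for the other traits); the count of
#' such records is reported via a message. This mirrors trait-specific
#' record counts in downstream genetic analyses.
#'
#' @param records data.frame with columns `dmy`, `fat_pct`, `protein_pct`,
#'   `cy_curd_pct`, `cy_solids_pct` and the six fatty-acid columns of
#'   [fa_profile()].
#' @return `records` with the trait columns appended.
#' @export
compute_all_eme <- function(records) {
  need <- c("dmy", "fat_pct", "protein_pct", "cy_curd_pct", "cy_solids_pct")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("records lack column(s): ", paste(missing, collapse = ", "))
  validate_fa_profile(records)

  records$ch4_dm <- methane_yield(records)
  records$ch4_cm <- methane_intensity_milk(records)
  records$dcmy <- corrected_milk_yield(records$dmy, records$fat_pct,
                                       records$protein_pct)
  records$dch4 <- daily_methane(records$ch4_cm, records$dcmy)
  records$dcy_curd <- records$dmy * records$cy_curd_pct / 100
  records$dcy_solids <- records$dmy * records$cy_solids_pct / 100

  ok_curd <- is.finite(records$dcy_curd) & records$dcy_curd > 0
  ok_sol <- is.finite(records$dcy_solids) & records$dcy_solids > 0
  records$ch4_cy_curd <- NA_real_
  records$ch4_cy_solids <- NA_real_
  records$ch4_cy_curd[ok_curd] <-
    methane_intensity_cheese(records$dch4[ok_curd], records$dcy_curd[ok_curd])
  records$ch4_cy_solids[ok_sol] <-
    methane_intensity_cheese(records$dch4[ok_sol], records$dcy_solids[ok_sol])
  n_drop <- sum(!ok_curd | !ok_sol)
  if (n_drop > 0)
    message(n_drop, " record(s) lack positive cheese yields; ",
            "cheese-intensity traits set to NA for them")
  records
}

# canonical trait name sets used across calibration and genetics
eme_trait_names <- function() c("ch4_dm", "ch4_cm", "dch4", "ch4_cy_curd",
                                "ch4_cy_solids")
informative_trait_names <- function() {
  c("c4_0", "c16_0iso", "c18_1_t10", "c18_1_t11", "c18_1_c9", "c18_2_c9c12",
    "cy_curd_pct", "cy_solids_pct", "dcmy")
}
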