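#' Read a period life table from CSV
#'
#' Expects a header `age,qx` with integer ages contiguous from 0 and
#' annual all-cause death probabilities in `[0,1]`.
#'
#' @param path CSV file path.
#' @return Data frame with columns `age` (integer) and `qx`.
#' @export
read_life_table <- function(path) {
  lt <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("age", "qx") %in% names(lt))) {
    stop("life table must have columns 'age' and 'qx'")
  }
  lt <- lt[order(lt$age), c("age", "qx")]
  lt$age <- as.integer(lt$age)
  if (!identical(lt$age, seq(0L, max(lt$age)))) {
    stop("life-table ages must be contiguous integers starting at 0")
  }
  lt
}

#' The bundled life table
#'
#' A synthetic period life table standing in for the Thai national table
#' (which the model needs but is not distributed with the package): a
#' Gompertz-Makeham hazard with an infant-mortality component, calibrated
#' so that life expectancy at birth is about 75 years and infant mortality
#' about 8 per 1000 live births, matching published Thai summary indices.
#' Replace it with an official table via the `life_table` argument of
#' [load_params()] for policy use.
#'
#' @return Data frame with columns `age` and `qx`, ages 0 to 100.
#' @export
default_life_table <- function() {
  read_life_table(system.file("extdata", "life_table_thai_synthetic.csv",
                              package = "tdascea", mustWork = TRUE))
}

# Annual death probability at an attained (possibly fractional) age,
# with lifetime closure: q = 1 at and beyond the closure age.
q_at_age <- function(life_table, age, max_age) {
  a <- floor(age)
  ifelse(a >= max_age, 1,
         life_table$qx[match(pmin(a, max(life_table$age)), life_table$age)])
}
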