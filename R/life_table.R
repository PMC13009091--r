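#' Generate a synthetic period life table
#'
#' Produces annual death probabilities from a Gompertz hazard,
#' `qx(age) = 1 - exp(-a * exp(b * age))`, clamped to \[0, 1\] and forced to
#' 1 at the maximum age so the cohort model is guaranteed to go extinct at
#' the end of the table. A smooth, age-increasing two-parameter law is the
#' standard demographic stand-in for a national period life table; the
#' defaults approximate recent US all-cause mortality at older ages.
#'
#' @param gompertz_a Positive baseline hazard scale (default 4e-5).
#' @param gompertz_b Positive log-hazard slope per year of age
#'   (default 0.092).
#' @param min_age,max_age Integer age range (contiguous rows).
#' @return data.frame with columns `age` and `qx` (annual death
#'   probability), non-decreasing in age, `qx = 1` at `max_age`.
#' @export
#' @examples
#' lt <- generate_life_table()
#' head(lt)
generate_life_table <- function(gompertz_a = 4e-5, gompertz_b = 0.092,
                                min_age = 40L, max_age = 100L) {
  if (!is.finite(gompertz_a) || gompertz_a <= 0 ||
      !is.finite(gompertz_b) || gompertz_b <= 0) {
    stop("generate_life_table: Gompertz parameters must be positive")
  }
  if (min_age >= max_age) stop("generate_life_table: min_age must be < max_age")
  age <- seq.int(min_age, max_age)
  qx <- 1 - exp(-gompertz_a * exp(gompertz_b * age))
  qx <- pmin(pmax(qx, 0), 1)
  qx[length(qx)] <- 1
  data.frame(age = as.integer(age), qx = qx)
}

#' Read a life table from CSV
#'
#' Expects columns `age` and `qx` with contiguous integer ages and annual
#' death probabilities in \[0, 1\]. A terminal probability below 1 is
#' allowed but the cohort then never fully goes extinct within the table;
#' the model clamps ages beyond the table to its last row.
#'
#' @param path CSV file with header `age,qx`.
#' @return data.frame with columns `age`, `qx`.
#' @export
load_life_table <- function(path) {
  if (!file.exists(path)) stop("life table not found: ", path)
  lt <- utils::read.csv(path)
  if (!all(c("age", "qx") %in% names(lt))) {
    stop("life table must have columns age and qx")
  }
  lt <- lt[order(lt$age), c("age", "qx")]
  if (any(diff(lt$age) != 1L)) stop("life table ages must be contiguous")
  if (any(lt$qx < 0 | lt$qx > 1)) stop("life table qx outside [0, 1]")
  lt
}

#' Write a life table to CSV
#' @param lt Life table data.frame (`age`, `qx`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_life_table <- function(lt, path) {
  utils::write.csv(lt[, c("age", "qx")], path, row.names = FALSE)
  invisible(path)
}

# internal: annual death probability at an age, clamped to the table range
qx_at <- function(lt, age) {
  i <- findInterval(age, lt$age)
  i <- pmin(pmax(i, 1L), nrow(lt))
  lt$qx[i]
}
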