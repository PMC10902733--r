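#' @useDynLib firearmMRP, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aggregate as.formula coef lm pnorm qnorm quantile
#'   rbinom rnorm rpois runif setNames terms vcov plogis qlogis predict
#'   rmultinom sd var
#' @importFrom utils read.csv write.csv
NULL

# Closed categorical code sets for the five stratification fields.
.codes <- list(
  gender     = c("man", "woman"),
  marital    = c("married", "not_married"),
  race       = c("white_aian", "other"),
  urbanicity = c("urban", "nonurban")
)

.strata_fields <- c("state", "gender", "marital", "race", "urbanicity")

# the 50 US states (no DC, no territories)
.state_codes <- c("AK", "AL", "AR", "AZ", "CA", "CO", "CT", "DE", "FL", "GA",
                  "HI", "IA", "ID", "IL", "IN", "KS", "KY", "LA", "MA", "MD",
                  "ME", "MI", "MN", "MO", "MS", "MT", "NC", "ND", "NE", "NH",
                  "NJ", "NM", "NV", "NY", "OH", "OK", "OR", "PA", "RI", "SC",
                  "SD", "TN", "TX", "UT", "VA", "VT", "WA", "WI", "WV", "WY")

#' Packaged state metadata
#'
#' Returns the packaged table of 50 US state codes with a flag indicating
#' whether the state contains at least one large densely populated county.
#' States without such a county contribute only nonurban strata to the
#' analytic frame.  The packaged choice of the seven flag-free states
#' (AK, ME, MT, ND, SD, VT, WY) is a documented fixture: the rule is the
#' contract, the list is editable.
#'
#' @return A data frame with columns `state_code` (character) and
#'   `has_urban_county` (0/1 integer).
#' @export
default_state_metadata <- function() {
  path <- system.file("extdata", "state_metadata.csv", package = "firearmMRP")
  read_state_metadata(path)
}

#' Read and validate a state metadata CSV
#'
#' @param path CSV with columns `state_code`, `has_urban_county`.
#' @return Validated data frame.
#' @export
read_state_metadata <- function(path) {
  if (!file.exists(path)) stop("missing input: ", path)
  md <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("state_code", "has_urban_county")
  miss <- setdiff(need, names(md))
  if (length(miss)) stop("state metadata missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(md$state_code))
    stop("duplicate state code(s): ",
         paste(unique(md$state_code[duplicated(md$state_code)]), collapse = ", "))
  if (!all(md$has_urban_county %in% c(0L, 1L)))
    stop("has_urban_county must be 0 or 1")
  md
}

#' Build the frame of analytic strata
#'
#' Enumerates every admissible stratum from the cross of state with binary
#' gender, marital status, race/ethnicity and urbanicity.  States flagged as
#' lacking a large densely populated county admit only `nonurban` strata.
#' Ordering is lexicographic on (state, gender, marital, race, urbanicity),
#' so the frame is deterministic across runs.  Under the packaged metadata
#' (43 urban-capable states x 16 cells + 7 urban-free states x 8 cells) the
#' frame has 744 strata.
#'
#' @param state_metadata Data frame as returned by [default_state_metadata()].
#'   Codes must be distinct and drawn from the 50 US state codes; reduced
#'   metadata (a subset of states) yields a reduced frame, used mainly for
#'   small worked examples.
#' @return An object of class `strata_frame`: a data frame with the five
#'   strata columns plus `stratum_id` (1-based position), and attribute
#'   `key_index` mapping the concatenated key to position.
#' @export
build_strata_frame <- function(state_metadata = default_state_metadata()) {
  if (!is.data.frame(state_metadata))
    stop("state_metadata must be a data frame")
  if (anyDuplicated(state_metadata$state_code))
    stop("duplicate state code(s): ",
         paste(unique(state_metadata$state_code[duplicated(state_metadata$state_code)]),
               collapse = ", "))
  bad <- setdiff(state_metadata$state_code, .state_codes)
  if (length(bad)) stop("unknown state code(s): ", paste(bad, collapse = ", "))

  grids <- lapply(seq_len(nrow(state_metadata)), function(i) {
    urb <- if (state_metadata$has_urban_county[i] == 1L)
      .codes$urbanicity else "nonurban"
    expand.grid(state = state_metadata$state_code[i],
                gender = .codes$gender,
                marital = .codes$marital,
                race = .codes$race,
                urbanicity = urb,
                stringsAsFactors = FALSE,
                KEEP.OUT.ATTRS = FALSE)
  })
  frame <- do.call(rbind, grids)
  ord <- do.call(order, frame[.strata_fields])
  frame <- frame[ord, , drop = FALSE]
  rownames(frame) <- NULL
  frame$stratum_id <- seq_len(nrow(frame))
  attr(frame, "key_index") <- setNames(frame$stratum_id, strata_key(frame))
  class(frame) <- c("strata_frame", "data.frame")
  frame
}

#' Concatenated stratum key
#'
#' @param x Data frame carrying the five strata columns.
#' @return Character vector of keys `state|gender|marital|race|urbanicity`.
#' @export
strata_key <- function(x) {
  do.call(paste, c(unname(as.list(x[.strata_fields])), sep = "|"))
}

#' Map records to positions in a strata frame
#'
#' @param frame A `strata_frame`.
#' @param x Data frame with the five strata columns.
#' @return Integer positions (NA where the key is not in the frame).
#' @export
match_strata <- function(frame, x) {
  idx <- attr(frame, "key_index")
  unname(idx[strata_key(x)])
}

#' @export
print.strata_frame <- function(x, ...) {
  cat("strata_frame:", nrow(x), "analytic strata over",
      length(unique(x$state)), "states\n")
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

.validate_pop <- function(pop) {
  need <- c(.strata_fields, "year", "population")
  miss <- setdiff(need, names(pop))
  if (length(miss)) stop("population table missing column(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(is.na(pop$population) | pop$population < 0)
  if (length(bad)) stop("negative or missing population count at row ", bad[1])
  invisible(pop)
}

#' Poststratification weights for a target population
#'
#' Computes weights proportional to stratum population size within a target
#' selection, for one year.  The weight of stratum `s` is
#' `pop(s, year) / sum(pop(., year))` over the selected strata, so weights
#' are nonnegative and sum to one.
#'
#' @param pop Population table (five strata columns + `year` + `population`).
#' @param frame A `strata_frame`.
#' @param target Named list selecting strata, e.g. `list(state = "MT")` or
#'   `list(race = "white_aian", urbanicity = "nonurban")`; `NULL` selects all
#'   strata (national target).  Values may be vectors.
#' @param year Calendar year of the population margin.
#' @return Numeric vector of length `nrow(frame)`: zero outside the target,
#'   weights summing to 1 within it.
#' @export
compute_weights <- function(pop, frame, target = NULL, year) {
  .validate_pop(pop)
  py <- pop[pop$year == year, , drop = FALSE]
  if (!nrow(py)) stop("no population rows for year ", year)
  pos <- match_strata(frame, py)
  if (anyNA(pos)) stop("population row ", which(is.na(pos))[1],
                       " does not map to a stratum in the frame")
  counts <- numeric(nrow(frame))
  counts[pos] <- counts[pos] + py$population
  sel <- select_strata(frame, target)
  w <- numeric(nrow(frame))
  tot <- sum(counts[sel])
  if (tot <= 0) stop("empty target population")
  w[sel] <- counts[sel] / tot
  w
}

#' Logical selector over a strata frame
#'
#' @param frame A `strata_frame`.
#' @param target Named list of field = value(s) restrictions; `NULL` selects
#'   everything.
#' @return Logical vector over strata.
#' @export
select_strata <- function(frame, target = NULL) {
  sel <- rep(TRUE, nrow(frame))
  if (is.null(target)) return(sel)
  if (!is.list(target) || is.null(names(target)) || any(names(target) == ""))
    stop("target must be a named list of strata fields")
  for (f in names(target)) {
    if (!f %in% .strata_fields)
      stop("unknown target field: ", f)
    vals <- target[[f]]
    known <- if (f == "state") unique(frame$state) else .codes[[f]]
    badv <- setdiff(vals, known)
    if (length(badv)) stop("unknown ", f, " code(s): ", paste(badv, collapse = ", "))
    sel <- sel & frame[[f]] %in% vals
  }
  sel
}
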