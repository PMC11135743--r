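# internal helpers shared across modules

# let data.table's [ dispatch work although only selected functions are
# imported
.datatable.aware <- TRUE

#' @importFrom data.table rbindlist
NULL

# fail with the list of missing columns, naming the offending table
.check_columns <- function(df, cols, what) {
  if (!is.data.frame(df)) stop("'", what, "' must be a data frame")
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0)
    stop("'", what, "' is missing required column(s): ",
         paste(missing, collapse = ", "))
  invisible(df)
}

# evaluate code under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
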