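#' Gas and physical constants
#'
#' The package ships its gas-specific constants (molar masses, solubility
#' coefficient sets, Schmidt-number polynomials, sustained-flux global
#' warming potentials) in a versioned plain-text YAML file so coefficient
#' provenance stays auditable.  `gas_constants()` reads and caches that
#' file; `gas_info()` returns the entry for one gas; `physical_constants()`
#' returns site-independent physical constants (von Karman constant, ideal
#' gas constant, standard temperature, Schmidt reference of 660).
#'
#' @param path Optional path to an alternative constants file.  Defaults to
#'   the file shipped with the package.
#' @return `gas_constants()`: a list with elements `version`, `gases`
#'   (named list keyed by gas) and `physical`.  `gas_info()`: the list for
#'   one gas.  `physical_constants()`: a named list.
#' @examples
#' gas_info("CH4")$molar_mass
#' physical_constants()$kappa
#' @export
gas_constants <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.constants_cache$default)) {
      return(.constants_cache$default)
    }
    path <- system.file("extdata", "gas_constants.yaml",
                        package = "coastalghg", mustWork = TRUE)
    out <- yaml::read_yaml(path)
    .constants_cache$default <- out
    return(out)
  }
  yaml::read_yaml(path)
}

.constants_cache <- new.env(parent = emptyenv())

#' @rdname gas_constants
#' @param gas Gas name, `"CO2"` or `"CH4"`.
#' @export
gas_info <- function(gas, path = NULL) {
  gas <- match_gas(gas)
  gas_constants(path)$gases[[gas]]
}

#' @rdname gas_constants
#' @export
physical_constants <- function(path = NULL) {
  gas_constants(path)$physical
}

match_gas <- function(gas) {
  if (!is.character(gas) || length(gas) != 1L) {
    abort("`gas` must be a single string (\"CO2\" or \"CH4\").")
  }
  gas <- toupper(gas)
  if (!gas %in% c("CO2", "CH4")) {
    abort(sprintf("Unknown gas \"%s\"; supported gases are CO2 and CH4.", gas))
  }
  gas
}

# run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}
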