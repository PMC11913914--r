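# Internal helpers shared across modules.

#' @importFrom withr with_seed
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All deterministic entry points go through this
# so that library use never clobbers a user's RNG.
local_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Deterministic derived seed, kept inside the 32-bit signed range.
derive_seed <- function(base_seed, index) {
  as.integer((as.double(base_seed) * 10007 + as.double(index) * 7919 + 1) %%
               2147483647)
}

stop_ennseg <- function(..., class = "ennseg_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

check_binary <- function(x, name = deparse(substitute(x))) {
  if (!all(x %in% c(0, 1))) {
    stop_ennseg(name, " must be binary (values in {0,1})",
                class = "ennseg_value_error")
  }
  invisible(x)
}

check_prob <- function(x, name = deparse(substitute(x))) {
  if (anyNA(x) || any(x < 0 | x > 1)) {
    stop_ennseg(name, " must contain probabilities in [0,1]",
                class = "ennseg_value_error")
  }
  invisible(x)
}

check_same_shape <- function(a, b, what = "inputs") {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(as.integer(da), as.integer(db))) {
    stop_ennseg(what, " must have identical shape (",
                paste(da, collapse = "x"), " vs ",
                paste(db, collapse = "x"), ")",
                class = "ennseg_shape_error")
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of a canonical JSON rendering; used as config hash in manifests.
hash_of <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, pretty = FALSE)
  unname(tools::md5sum(f))
}
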