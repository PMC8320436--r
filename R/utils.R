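# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# run expr with a private RNG stream so callers' .Random.seed is untouched
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      if (exists(".Random.seed", envir = env, inherits = FALSE))
        rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

as_signal_matrix <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  storage.mode(x) <- "double"
  x
}

significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p)   ~ NA_character_,
    p <= 0.001 ~ "***",
    p <= 0.01  ~ "**",
    p <= 0.05  ~ "*",
    TRUE       ~ ""
  )
}

abort_semg <- function(msg, class) {
  rlang::abort(msg, class = paste0("semgmap_", class, "_error"))
}
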