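# Internal helpers shared across modules.

# Seed a block of code and restore the caller's RNG state afterwards.
# Usage: restore <- push_seed(seed); on.exit(restore(), add = TRUE)
push_seed <- function(seed) {
  if (is.null(seed)) {
    return(function() invisible(NULL))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  set.seed(as.integer(seed))
  function() {
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
    invisible(NULL)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Uniform draw from an explicit value set; sample() misbehaves for length-1
# numeric vectors, so index explicitly.
draw_from <- function(values, n) {
  values[sample.int(length(values), n, replace = TRUE)]
}

# Number of spikes (sorted) falling in each half-open window [start, end).
count_in_windows <- function(spikes, starts, ends) {
  eps <- 1e-12
  findInterval(ends - eps, spikes) - findInterval(starts - eps, spikes)
}

# Stable short hash of any jsonlite-serialisable object (provenance sidecars).
config_hash <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                     force = TRUE))
  b <- utf8ToInt(s)
  m <- 2147483647
  h <- 0
  for (ch in b) h <- (h * 31 + ch) %% m
  sprintf("%x", h)
}

# Tuning factor on the doubled-angle scale, normalised to peak 1.
# Orientation has period 180 deg, hence cos(2 * delta).
vm_tuning <- function(theta_deg, theta_pref_deg, kappa) {
  exp(kappa * (cospi(2 * (theta_deg - theta_pref_deg) / 180) - 1))
}
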