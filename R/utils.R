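# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards. All stochastic operations in the
# package route through this so no call mutates global RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != round(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Coerce class labels to integer 0/1 with 1 = "high". Accepts factor or
# character ("high"/"low"), logical, or numeric 0/1.
as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c("high", "low"))
    if (length(bad) > 0) {
      stop("character labels must be 'high'/'low'; found: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    return(as.integer(labels == "high"))
  }
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) {
      stop("numeric labels must be 0/1", call. = FALSE)
    }
    return(as.integer(labels))
  }
  stop("unsupported label type", call. = FALSE)
}

# Validate and coerce a binary 3D grid to a logical array.
as_mask <- function(x, name = "mask") {
  if (is.null(dim(x)) || length(dim(x)) != 3L) {
    stop("`", name, "` must be a 3D array", call. = FALSE)
  }
  if (is.logical(x)) return(x)
  if (is.numeric(x)) {
    if (any(!x %in% c(0, 1))) {
      stop("`", name, "` must be binary (0/1)", call. = FALSE)
    }
    m <- x != 0
    return(array(m, dim(x)))
  }
  stop("`", name, "` must be logical or numeric 0/1", call. = FALSE)
}

# Truncated-normal draws on [lo, hi] by inverse-CDF; vectorized over mean.
rtrunc_norm <- function(n, mean, sd, lo = 0, hi = 100) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# Sub-seed derivation kept below .Machine$integer.max.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + k) %% 2147483647)
}
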