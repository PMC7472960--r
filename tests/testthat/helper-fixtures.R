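# shared fixtures and independent oracles, built in code

tiny_grid <- function(shape = c(6, 6, 6), spacing = c(2, 2, 2), ...) {
  make_grid(shape, spacing, ...)
}

default_grid <- function() make_grid(c(45, 54, 45), c(4, 4, 4))

# minimal well-formed record row(s)
make_records <- function(n, ...) {
  out <- data.frame(
    patient_id = sprintf("T%03d", seq_len(n)),
    age = 50, sex = "female", who_grade = "I",
    location_label = "convexity", eor = "GTR", recurrence = "no",
    followup_time = 60,
    p53 = "negative", Ki67_gt5pct = "negative", EMA = "positive",
    PR = "positive", CD34 = "negative", mask_path = NA_character_,
    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  out
}

# independent two-tailed Fisher oracle: exhaustive enumeration through
# stats::dhyper (never touches the package's log-space path)
oracle_fisher <- function(a, b, c, d, rel_tol = 1e-7) {
  nA <- a + c; nB <- b + d; k <- a + b
  xs <- max(0, k - nB):min(k, nA)
  probs <- stats::dhyper(xs, nA, nB, k)
  min(1, sum(probs[probs <= probs[xs == a] * (1 + rel_tol)]))
}

# brute-force per-voxel overlap count via dense arrays
oracle_counts <- function(masks) {
  Reduce(`+`, lapply(masks, function(m) mask_array(m) + 0L))
}

random_mask <- function(id, grid, density = 0.2) {
  nvox <- prod(grid$shape)
  lesion_mask(id, grid,
              indices = sample.int(nvox, max(1L, round(density * nvox))))
}
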