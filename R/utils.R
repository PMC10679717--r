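# Element property tables and small numeric helpers shared across modules.

# Bondi van der Waals radii (Angstrom); fallback 1.70 for unlisted elements.
.vdw_radii <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, P = 1.80, S = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, K = 2.75, NA. = 2.27,
  MG = 1.73, ZN = 1.39
)

# Covalent radii (Angstrom), Cordero et al. consensus values.
.cov_radii <- c(
  H = 0.31, C = 0.76, N = 0.71, O = 0.66, P = 1.07, S = 1.05,
  F = 0.57, CL = 1.02, BR = 1.20, I = 1.39, K = 2.03, NA. = 1.66
)

.element_lookup <- function(table, element, default) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  out <- unname(table[key])
  out[is.na(out)] <- default
  out
}

vdw_radius <- function(element) .element_lookup(.vdw_radii, element, 1.70)
covalent_radius <- function(element) .element_lookup(.cov_radii, element, 0.77)

# Boltzmann constant in kcal mol^-1 K^-1 (toy-engine energy units).
.kB <- 0.0019872041

# Infer an element symbol from a PDB atom name when the element column is
# blank: strip digits/primes, take the leading alphabetic token; two-letter
# halogens are recognised explicitly.
guess_element <- function(name) {
  nm <- toupper(gsub("[^A-Za-z]", "", name))
  two <- substr(nm, 1, 2)
  ifelse(two %in% c("CL", "BR", "NA", "MG", "ZN"), two, substr(nm, 1, 1))
}

# Pairwise Euclidean distances between the rows of two n x 3 matrices.
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

vec_angle <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# Angle at vertex b (degrees) for points a-b-c.
point_angle <- function(a, b, c) vec_angle(a - b, c - b)

# Derive a child RNG seed from a master seed and a stream index without
# consuming the global RNG state; counter-based so adding one consumer does
# not shift the streams of the others. Result fits in a 32-bit integer.
derive_seed <- function(seed, stream) {
  s <- (as.double(seed) * 2654435.0 + as.double(stream) * 40503.0 + 97.0)
  as.integer(s %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
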