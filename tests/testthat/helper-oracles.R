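## Independent oracles and small builders used across the suite. The
## oracles deliberately avoid the package's own code paths: the
## superposition oracle is quaternion-based (Horn) where the package uses
## SVD (Kabsch); the clash and line-fit oracles are naive brute force.

## Horn's closed-form absolute orientation: optimal rotation as the top
## eigenvector of the 4x4 quaternion cross-covariance matrix.
quaternion_superpose_rmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  M <- crossprod(Pc, Qc)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,       Szx - Sxz,       Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz, Sxy + Syx,       Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx,       Szx + Sxz,       Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  moved <- Pc %*% t(R)
  sqrt(mean(rowSums((moved - Qc)^2)))
}

## Uniform random rotation from a normalized Gaussian quaternion.
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
}

random_rigid <- function(t_sd = 15) {
  rigid_transform(random_rotation(), rnorm(3, sd = t_sd))
}

## Naive all-pairs clash scan (the package vectorizes; this does not).
brute_clash <- function(model, cutoff = 4, exclude_bonded = 2L) {
  ca <- model$atoms[model$atoms$elety == "CA", ]
  n <- nrow(ca)
  count <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((unlist(ca[i, c("x", "y", "z")]) -
                       unlist(ca[j, c("x", "y", "z")]))^2))
      if (d >= cutoff) next
      if (ca$chain[i] == ca$chain[j] &&
          abs(ca$resno[i] - ca$resno[j]) <= exclude_bonded) next
      count <- count + 1L
    }
  }
  count
}

## Brute-force RMS perpendicular deviation from the total-least-squares
## line, via the eigendecomposition of the covariance (independent of the
## package's prcomp route).
brute_line_rms <- function(xyz) {
  ctr <- colMeans(xyz)
  rel <- sweep(xyz, 2, ctr)
  ev <- eigen(crossprod(rel) / nrow(rel), symmetric = TRUE)
  u <- ev$vectors[, 1]
  perp2 <- rowSums(rel^2) - (rel %*% u)^2
  sqrt(mean(pmax(perp2, 0)))
}

## Single-chain sub-model over a residue subset.
sub_model <- function(model, residues, chain_id = NULL) {
  a <- model$atoms[model$atoms$resno %in% residues, , drop = FALSE]
  if (!is.null(chain_id)) a$chain <- chain_id
  structure_model(a, title = model$title, source_id = "fragment")
}

## A Calpha-only model from an n x 3 coordinate matrix.
point_model <- function(xyz, chain = "A", resno = seq_len(nrow(xyz))) {
  structure_model(data.frame(chain = chain, resno = resno, resid = "ALA",
                             elety = "CA", x = xyz[, 1], y = xyz[, 2],
                             z = xyz[, 3], stringsAsFactors = FALSE))
}

xyz_of <- function(model) as.matrix(model$atoms[, c("x", "y", "z")])

rotation_angle_deg <- function(R) {
  acos(pmin(1, pmax(-1, (sum(diag(R)) - 1) / 2))) * 180 / pi
}

## Directory where locally supplied copies of deposited reference
## structures are looked up by the acceptance tests.
reference_path <- function(file) {
  p <- system.file("extdata", "reference", file, package = "smcrod")
  if (nzchar(p)) p else file.path("inst", "extdata", "reference", file)
}
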