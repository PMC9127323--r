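# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# --- quaternion (Horn) superposition oracle --------------------------------
# Optimal rotation from x onto y via the largest eigenvector of the 4x4
# quaternion cross-covariance matrix; independent of the SVD route.
quaternion_superpose <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  xc <- sweep(x, 2, cx); yc <- sweep(y, 2, cy)
  S <- t(xc) %*% yc
  K <- matrix(0, 4, 4)
  K[1, 1] <- S[1, 1] + S[2, 2] + S[3, 3]
  K[1, 2] <- K[2, 1] <- S[2, 3] - S[3, 2]
  K[1, 3] <- K[3, 1] <- S[3, 1] - S[1, 3]
  K[1, 4] <- K[4, 1] <- S[1, 2] - S[2, 1]
  K[2, 2] <- S[1, 1] - S[2, 2] - S[3, 3]
  K[2, 3] <- K[3, 2] <- S[1, 2] + S[2, 1]
  K[2, 4] <- K[4, 2] <- S[1, 3] + S[3, 1]
  K[3, 3] <- -S[1, 1] + S[2, 2] - S[3, 3]
  K[3, 4] <- K[4, 3] <- S[2, 3] + S[3, 2]
  K[4, 4] <- -S[1, 1] - S[2, 2] + S[3, 3]
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w <- q[1]; xq <- q[2]; yq <- q[3]; zq <- q[4]
  rot <- matrix(c(
    1 - 2 * (yq^2 + zq^2), 2 * (xq * yq - w * zq), 2 * (xq * zq + w * yq),
    2 * (xq * yq + w * zq), 1 - 2 * (xq^2 + zq^2), 2 * (yq * zq - w * xq),
    2 * (xq * zq - w * yq), 2 * (yq * zq + w * xq), 1 - 2 * (xq^2 + yq^2)),
    3, 3, byrow = TRUE)
  trans <- cy - as.vector(rot %*% cx)
  fitted <- sweep(x %*% t(rot), 2, trans, "+")
  list(rotation = rot, translation = trans,
       rmsd = sqrt(mean(rowSums((fitted - y)^2))))
}

# --- exhaustive affine-gap global alignment oracle -------------------------
# Needleman-Wunsch with affine gaps, replicating the cost convention of
# Biostrings::pairwiseAlignment (a gap of length L costs
# gapOpening + gapExtension * L). Returns the optimal score only.
nw_affine_score <- function(a, b, mat, go = 10, ge = 4) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- Ix <- Iy <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(go + ge * i)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(go + ge * j)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - go - ge, Ix[i, j + 1] - ge)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - go - ge, Iy[i + 1, j] - ge)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# direct RMSD formula (no superposition)
direct_rmsd <- function(x, y) sqrt(mean(rowSums((x - y)^2)))

# peptide bond-length RMS deviation from ideal values, computed directly
# from an atom table (independent of the package restraint machinery)
peptide_bond_rms <- function(s) {
  pep <- s$atoms[s$atoms$chain == "P", ]
  ideal <- list(c("N", "CA", 1.46), c("CA", "C", 1.52), c("C", "O", 1.23),
                c("CA", "CB", 1.53))
  get1 <- function(r, at) {
    row <- pep[pep$resno == r & pep$atom == at, ]
    if (nrow(row) != 1) return(NULL)
    as.numeric(row[, c("x", "y", "z")])
  }
  devs <- c()
  for (r in unique(pep$resno)) {
    for (b in ideal) {
      p <- get1(r, b[[1]]); q <- get1(r, b[[2]])
      if (!is.null(p) && !is.null(q)) {
        devs <- c(devs, sqrt(sum((p - q)^2)) - as.numeric(b[[3]]))
      }
    }
    p <- get1(r, "C"); q <- get1(r + 1, "N")
    if (!is.null(p) && !is.null(q)) {
      devs <- c(devs, sqrt(sum((p - q)^2)) - 1.33)
    }
  }
  sqrt(mean(devs^2))
}

# Biostrings PAM30 (independent copy of the published matrix)
biostrings_pam30 <- function() {
  e <- new.env()
  utils::data("PAM30", package = "Biostrings", envir = e)
  e$PAM30
}

biostrings_blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}
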