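# Independent oracles and hand-built fixtures used across the suite.
# These deliberately re-derive quantities with naive loops so they share no
# code path with the package implementation.

# Brute-force observed field: explicit double loop over all residue pairs.
brute_observed <- function(records, cutoff = 9, include_self = TRUE) {
  n <- nrow(records)
  raw <- numeric(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j && !include_self) next
      r <- sqrt((records$x[i] - records$x[j])^2 +
                (records$y[i] - records$y[j])^2 +
                (records$z[i] - records$z[j])^2)
      if (r >= cutoff) next
      t2 <- (r / cutoff)^2
      w <- 1 - 0.5 * (7 * t2 - 9 * t2^2 + 5 * t2^3 - t2^4)
      raw[i] <- raw[i] + records$h[j] * w
    }
  }
  raw / sum(raw)
}

# Scalar Gaussian evaluation at each point, one residue at a time.
brute_theoretical <- function(xyz, frame) {
  raw <- apply(xyz, 1L, function(p) {
    v <- as.numeric(t(frame$axes) %*% (p - frame$center))
    exp(-v[1]^2 / (2 * frame$sigma[1]^2)) *
      exp(-v[2]^2 / (2 * frame$sigma[2]^2)) *
      exp(-v[3]^2 / (2 * frame$sigma[3]^2))
  })
  raw / sum(raw)
}

# Maximum |projection| per axis by explicit loops.
brute_sigma <- function(xyz, frame, margin = 0) {
  ext <- c(0, 0, 0)
  for (k in 1:3) {
    for (i in seq_len(nrow(xyz))) {
      p <- abs(sum((xyz[i, ] - frame$center) * frame$axes[, k]))
      if (p > ext[k]) ext[k] <- p
    }
  }
  (ext + margin) / 3
}

# Elementwise KL summation.
brute_kl <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) if (p[i] > 0) s <- s + p[i] * log2(p[i] / q[i])
  s
}

# Uniform random rotation matrix (QR of a Gaussian matrix, det +1).
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3L))
  r <- qr.Q(qr_)
  if (det(r) < 0) r[, 1L] <- -r[, 1L]
  r
}

transform_records <- function(records, rot, shift) {
  xyz <- cbind(records$x, records$y, records$z) %*% t(rot)
  records$x <- xyz[, 1L] + shift[1L]
  records$y <- xyz[, 2L] + shift[2L]
  records$z <- xyz[, 3L] + shift[3L]
  records
}

# Random residue records in a blob, standard residue names.
random_records <- function(n, seed = 1, spread = 8) {
  set.seed(seed)
  aa <- sample(names(hydro_scale()$values), n, replace = TRUE)
  df <- data.frame(chain = "A", resno = seq_len(n), icode = "", aa3 = aa,
                   x = stats::rnorm(n, sd = spread),
                   y = stats::rnorm(n, sd = spread),
                   z = stats::rnorm(n, sd = spread),
                   h = NA_real_, stringsAsFactors = FALSE)
  assign_hydrophobicity(oildrop:::.as_fod_residues(df), hydro_scale())
}

# Build a profile with prescribed O (for identity checks).
profile_with_O <- function(base, O) {
  oildrop:::.new_profile(base$residues, raw_T = base$raw_T, raw_O = O,
                         frame = base$frame)
}

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          occ = 1, alt = " ", icode = " ", elem = NULL) {
  if (is.null(elem)) elem <- substr(trimws(name), 1L, 1L)
  sprintf("ATOM  %5d %-4s%s%3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial, name, alt, resname, chain, resno, icode, x, y, z, occ, 0,
          elem)
}

# Hand-written three-residue PDB: GLY(2 atoms)-ALA(1)-LEU(8).
write_tiny_pdb <- function(path) {
  leu <- rbind(c(10, 0, 0), c(11.5, 0, 0), c(12, 1.3, 0), c(13.2, 1.4, 0.2),
               c(11.9, -1.2, 0.8), c(12.8, -2.4, 0.6), c(14.1, -2.2, 1.3),
               c(12.2, -3.7, 1.0))
  lines <- c(
    pdb_atom_line(1, " N  ", "GLY", "A", 1, 0, 0, 0),
    pdb_atom_line(2, " CA ", "GLY", "A", 1, 2, 0, 0),
    pdb_atom_line(3, " CA ", "ALA", "A", 2, 5, 1, 1),
    sapply(seq_len(nrow(leu)), function(i)
      pdb_atom_line(3 + i, c(" N  ", " CA ", " C  ", " O  ", " CB ", " CG ",
                             " CD1", " CD2")[i],
                    "LEU", "A", 3, leu[i, 1], leu[i, 2], leu[i, 3])),
    "TER",
    "HETATM   99  O   HOH A 101      20.000  20.000  20.000  1.00  0.00           O",
    "END")
  writeLines(lines, path)
  list(path = path, leu_mean = colMeans(leu))
}
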