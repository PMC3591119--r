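# Shared fixture builders: everything is generated in code at test time.

# One PDB ATOM record for a C-alpha (fixed columns, altloc at column 17).
pdb_ca_line <- function(serial, resno, x, y, z, chain = "A", alt = " ",
                        resid = "ALA", icode = " ") {
  sprintf("ATOM  %5d  CA %1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, alt, resid, chain, resno, icode, x, y, z)
}

write_pdb_fixture <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

# Three collinear CA at 3.8 A spacing on chain A.
three_res_pdb <- function() {
  write_pdb_fixture(c(
    pdb_ca_line(1, 1, 0, 0, 0),
    pdb_ca_line(2, 2, 3.8, 0, 0),
    pdb_ca_line(3, 3, 7.6, 0, 0)))
}

# Random proper rotation built from a normalized Gaussian quaternion.
rand_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

rand_transform <- function(tmax = 10) {
  rigid_transform(rand_rotation(), runif(3, -tmax, tmax))
}

# Random strictly monotone alignment of an m x n instance.
rand_monotone_alignment <- function(m, n, scheme = "none") {
  k <- sample.int(min(m, n), 1)
  alignment(sort(sample.int(m, k)), sort(sample.int(n, k)), scheme = scheme)
}

# Axis-angle rotation helper (degrees).
axis_rotation <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  q <- c(cos(th / 2), sin(th / 2) * axis)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
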