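# Independent oracles and fixture builders. Everything here stays independent
# of the code paths it checks: meshes are constructed explicitly, AUROC is
# counted pairwise, volumes come from closed forms.

# hand-built unit cube mesh: 8 vertices, 12 outward-oriented triangles
unit_cube_mesh <- function() {
  v <- rbind(c(0,0,0), c(1,0,0), c(1,1,0), c(0,1,0),
             c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))
  f <- rbind(c(1,3,2), c(1,4,3), c(5,6,7), c(5,7,8),
             c(1,2,6), c(1,6,5), c(4,7,3), c(4,8,7),
             c(1,5,8), c(1,8,4), c(2,3,7), c(2,7,6))
  surface_mesh(v, f)
}

# icosphere: subdivided icosahedron projected to radius r — an analytic-sphere
# mesh oracle built without touching the package's voxel pipeline
icosphere <- function(r = 1, subdiv = 4) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1,12,6), c(1,6,2), c(1,2,8), c(1,8,11), c(1,11,12),
    c(2,6,10), c(6,12,5), c(12,11,3), c(11,8,7), c(8,2,9),
    c(4,10,5), c(4,5,3), c(4,3,7), c(4,7,9), c(4,9,10),
    c(5,10,6), c(3,5,12), c(7,3,11), c(9,7,8), c(10,9,2))
  for (s in seq_len(subdiv)) {
    cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(cache[[key]])) return(cache[[key]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      cache[[key]] <- nrow(v)
      nrow(v)
    }
    nf <- matrix(0L, 0, 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i,1]; b <- f[i,2]; c <- f[i,3]
      ab <- midpoint(a,b); bc <- midpoint(b,c); ca <- midpoint(c,a)
      nf <- rbind(nf, c(a,ab,ca), c(b,bc,ab), c(c,ca,bc), c(ab,bc,ca))
    }
    f <- nf
  }
  v <- v * r / sqrt(rowSums(v^2))
  surface_mesh(v, f)
}

# brute-force O(n^2) Mann-Whitney AUROC with ties counted 1/2
auroc_pairwise <- function(pos, neg, lower_is_positive = TRUE) {
  cmp <- outer(pos, neg, function(p, q) {
    if (lower_is_positive) (p < q) + 0.5 * (p == q) else (p > q) + 0.5 * (p == q)
  })
  mean(cmp)
}

# write a labeled NIfTI volume for load_mask tests
write_label_volume <- function(arr, path, spacing = c(1, 1, 1)) {
  write_nifti(arr, path, spacing = spacing)
  path
}
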