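## Shared test helpers: small constructed trajectories and geometry tools.

## rotation matrix taking unit vector a onto unit vector b
rot_onto <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  s <- sqrt(sum(v^2)); cth <- sum(a * b)
  if (s < 1e-12) {
    if (cth > 0) return(diag(3))
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    p <- p - sum(p * a) * a; p <- p / sqrt(sum(p^2))
    return(2 * outer(p, p) - diag(3) + 2 * outer(a, a))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K * ((1 - cth) / s^2)
}

## single-tail chain topology with n carbons
chain_topology <- function(n = 10) {
  lipid_topology("CHN", paste0("C", seq_len(n)),
                 tail1_atoms = paste0("C", seq_len(n)),
                 tail2_atoms = character(0), headgroup_atoms = "C1",
                 splay_vertex = "C1", glycerol_vector_atoms = c("C1", "C2"),
                 g3_selection = paste0("C", seq_len(n)))
}

## wrap per-frame coordinate matrices (list or single matrix) into a traj
traj_from_coords <- function(xyz, topology, n_lipids, box = c(100, 100, 100),
                             dt = 1) {
  if (is.matrix(xyz)) xyz <- list(xyz)
  n_frames <- length(xyz)
  co <- array(0, c(nrow(xyz[[1]]), 3, n_frames))
  for (f in seq_len(n_frames)) co[, , f] <- xyz[[f]]
  membrane_trajectory(co, matrix(rep(box, each = n_frames), ncol = 3),
                      times = (seq_len(n_frames) - 1) * dt,
                      topology = topology, n_lipids = n_lipids,
                      atom_names = rep(topology$atom_names, n_lipids))
}

## an all-trans chain whose zigzag axis is exactly `axis`
trans_chain_along <- function(n, axis, seed = 1) {
  ch <- generate_chain(n, 0, seed = seed)
  a0 <- ch[3, ] - ch[1, ]
  ch %*% t(rot_onto(a0, axis))
}

## brute-force g3 triple-loop oracle with the package's binning convention
g3_oracle <- function(xyz_frames, cutoff = 15, nr = 201, na = 101) {
  h <- matrix(0, nr, na)
  for (xyz in xyz_frames) {
    n <- nrow(xyz)
    for (b in seq_len(n)) {
      d <- sqrt(rowSums(sweep(xyz, 2, xyz[b, ])^2))
      d[b] <- Inf
      a <- which.min(d)                       # lowest index on ties
      va <- (xyz[a, ] - xyz[b, ]) / d[a]
      for (cc in seq_len(n)) {
        if (cc == b) next
        vc <- xyz[cc, ] - xyz[b, ]
        r <- sqrt(sum(vc^2))
        if (r <= 0 || r > cutoff) next
        ct <- min(1, max(-1, sum(va * vc) / r))
        ri <- min(max(ceiling(r / cutoff * nr), 1), nr)
        ci <- min(floor((ct + 1) / 2 * na) + 1, na)
        h[ri, ci] <- h[ri, ci] + 1
      }
    }
  }
  h / sum(h)
}

## tiny two-lipid system with a donor/acceptor pair at given geometry
hbond_pair_traj <- function(d, ang_deg) {
  tp <- lipid_topology("HBT", c("O1", "HO1", "O2", "C1", "C3"),
                       tail1_atoms = c("C1", "C3", "O2"),
                       tail2_atoms = character(0), headgroup_atoms = "O1",
                       donors = list(c("O1", "HO1")), acceptors = c("O1", "O2"),
                       splay_vertex = "C1",
                       glycerol_vector_atoms = c("C1", "C3"))
  ang <- ang_deg * pi / 180
  xyz <- rbind(
    c(0, 0, 0),                                  # lipid 1 O1 (donor)
    c(cos(ang), sin(ang), 0) * 0.97,             # HO1
    c(20, 20, 5), c(20, 20, 8), c(20, 21, 8),    # O2, C1, C3 (far away)
    c(30, 30, 10), c(30, 30.97, 10),             # lipid 2 O1, HO1 (far)
    c(d, 0, 0),                                  # lipid 2 O2 (acceptor)
    c(31, 30, 12), c(31, 31, 12))
  traj_from_coords(xyz, tp, 2, box = c(60, 60, 60))
}
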