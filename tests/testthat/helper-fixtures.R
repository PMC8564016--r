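# Fixture builders shared across the suite. Everything is generated in code;
# no stored data files.

rel_err <- function(a, b) abs(a - b) / pmax(abs(b), .Machine$double.eps)

# Single-branch tree realizing an exact three-segment lesion with
# linear-in-radius tapers, plus the matching lesion record. Used to compare
# the closed-form drop assembly against fine-grid quadrature: both routes see
# exactly the same geometry.
linear_lesion_fixture <- function(r_p, r_s, r_d, L_ps, L_ss, L_sd,
                                  n_per_seg = 300) {
  stopifnot(r_s <= r_p, r_s <= r_d)
  s1 <- seq(0, L_ps, length.out = n_per_seg + 1)
  s2 <- seq(L_ps, L_ps + L_ss, length.out = n_per_seg + 1)
  s3 <- seq(L_ps + L_ss, L_ps + L_ss + L_sd, length.out = n_per_seg + 1)
  r1 <- r_p + (r_s - r_p) * s1 / L_ps
  r2 <- rep(r_s, length(s2))
  r3 <- r_s + (r_d - r_s) * (s3 - (L_ps + L_ss)) / L_sd
  s <- c(s1, s2[-1], s3[-1])
  r <- c(r1, r2[-1], r3[-1])
  b <- branch("les", s, pi * r^2)
  L <- L_ps + L_ss + L_sd
  l <- lesion(branch_id = "les", s_prox = 0, s_dist = L,
              s_throat_start = L_ps, s_throat_end = L_ps + L_ss,
              A_p = pi * r_p^2, A_s = pi * r_s^2, A_d = pi * r_d^2,
              L = L, L_ps = L_ps, L_sd = L_sd,
              alpha = atan((r_p - r_s) / L_ps) * 180 / pi,
              beta = atan((r_d - r_s) / L_sd) * 180 / pi,
              ds = 1 - r_s / max(r_p, r_d))
  list(branch = b, lesion = l, tree = coronary_tree(list(b), "les"))
}

# Random bifurcating tree with stenoses dropped on random branches.
random_stenosed_tree <- function(generations = 3, seed = 1) {
  set.seed(seed)
  tr <- make_bifurcating_tree(generations,
                              root_radius = runif(1, 1.6, 2.2),
                              child_ratios = runif(2, 0.6, 0.9),
                              step = 0.5)
  ids <- names(tr$branches)
  hit <- sample(ids, min(2, length(ids)))
  for (id in hit) {
    len <- diff(range(tr$branches[[id]]$s))
    if (len < 14) next
    tr <- add_stenosis(tr, id, ds_true = runif(1, 0.3, 0.7), L = 8,
                       L_ps = 3, L_sd = 3,
                       center_s = runif(1, 5, len - 5))
  }
  tr
}

default_fluid <- list(mu = 3.5e-3, rho = 1060)
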