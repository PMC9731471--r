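## Independent oracles and world builders used across the test files.

## Brute-force flood-fill over the raw bond fields of a world: adjacency from
## dimer bonds, receptor pairs sharing one ligand and pairs sharing one
## crosslinker.  Kept deliberately independent of build_bond_graph()/census()
## and of the C++ engine's union-find.
floodfill_component_sizes <- function(world) {
  nR <- length(world$rx)
  adj <- vector("list", nR)
  push <- function(a, b) {
    adj[[a]] <<- c(adj[[a]], b)
    adj[[b]] <<- c(adj[[b]], a)
  }
  for (i in seq_len(nR)) {
    j <- world$dimer[i]
    if (!is.na(j) && j > i) push(i, j)
  }
  both <- !is.na(world$ls1) & !is.na(world$ls2)
  for (l in which(both)) push(world$ls1[l], world$ls2[l])
  both <- !is.na(world$xs1) & !is.na(world$xs2)
  for (x in which(both)) push(world$xs1[x], world$xs2[x])
  seen <- logical(nR)
  sizes <- integer(0)
  for (start in seq_len(nR)) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    size <- 0L
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      size <- size + 1L
      for (w in adj[[v]]) {
        if (!seen[w]) {
          seen[w] <- TRUE
          queue <- c(queue, w)
        }
      }
    }
    sizes <- c(sizes, size)
  }
  sort(sizes, decreasing = TRUE)
}

## A consistent world with random positions, phosphorylation and bonds.
random_bonded_world <- function(nR = 30, nL = 10, nX = 10, seed = 1) {
  set.seed(seed)
  cfg <- abm_config(n_receptors = nR, n_crosslinkers = nX, n_ligands = nL,
                    ticks = 1)
  world <- init_world(cfg)
  world$phos <- as.integer(stats::runif(nR) < 0.5)
  ## random dimer pairing over a subset of receptors
  free <- sample(nR)
  n_pairs <- sample.int(nR %/% 3 + 1L, 1L) - 1L
  for (k in seq_len(n_pairs)) {
    a <- free[2 * k - 1]
    b <- free[2 * k]
    world$dimer[a] <- b
    world$dimer[b] <- a
  }
  ## random ligand / crosslinker site occupancy (receptors hold <= 1 each)
  lig_free <- which(is.na(world$lig))
  for (l in seq_len(nL)) {
    for (site in c("ls1", "ls2")) {
      if (length(lig_free) && stats::runif(1) < 0.5) {
        r <- lig_free[sample.int(length(lig_free), 1L)]
        world[[site]][l] <- r
        world$lig[r] <- l
        lig_free <- setdiff(lig_free, r)
      }
    }
  }
  xl_free <- which(is.na(world$xl) & world$phos == 1L)
  for (x in seq_len(nX)) {
    for (site in c("xs1", "xs2")) {
      if (length(xl_free) && stats::runif(1) < 0.5) {
        r <- xl_free[sample.int(length(xl_free), 1L)]
        world[[site]][x] <- r
        world$xl[r] <- x
        xl_free <- setdiff(xl_free, r)
      }
    }
  }
  world
}

## Fraction of receptors in complexes of size >= k from an ensemble final
## summary.
frac_in_size_ge <- function(final, k) {
  f <- function(x) final$mean[final$field == x]
  total <- f("frac_receptors_gt4")
  for (s in 4:1) {
    if (s >= k) total <- total + f(paste0("frac_receptors_in_size_", s))
  }
  total
}
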