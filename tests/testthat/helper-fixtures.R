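# Shared fixtures and independent oracles. Everything here is deliberately
# naive (enumeration, shoelace by hand) so that package results are checked
# against code that shares no internals with the implementation.

# Plus-sign polygon: three unit squares in a row, one above and one below
# the centre square. 12 vertices, area 5.
plus_polygon <- function() {
  rbind(c(0, 0), c(1, 0), c(1, -1), c(2, -1), c(2, 0), c(3, 0),
        c(3, 1), c(2, 1), c(2, 2), c(1, 2), c(1, 1), c(0, 1))
}

unit_square <- function() rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))

regular_polygon <- function(k, r = 1) {
  th <- 2 * pi * (seq_len(k) - 1) / k
  cbind(r * cos(th), r * sin(th))
}

# Star-shaped random polygon (simple by construction): sorted angles,
# random radii.
random_star_polygon <- function(n_vertices = 12) {
  th <- sort(stats::runif(n_vertices, 0, 2 * pi))
  r <- stats::runif(n_vertices, 0.2, 1)
  cbind(r * cos(th), r * sin(th))
}

# Independent shoelace area oracle.
oracle_area <- function(xy) {
  n <- nrow(xy)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + xy[i, 1] * xy[j, 2] - xy[j, 1] * xy[i, 2]
  }
  as.numeric(abs(s) / 2)
}

oracle_perimeter <- function(xy) {
  n <- nrow(xy)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + sqrt(sum((xy[j, ] - xy[i, ])^2))
  }
  as.numeric(s)
}

# Brute-force branch counting on a 1-px skeleton mask: count 8-neighbours
# per pixel, delete junction pixels (>= 3 neighbours), count remaining
# connected components by naive repeated scanning.
oracle_branch_count <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  deg <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!sk[r, c]) next
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc && sk[rr, cc])
        deg[r, c] <- deg[r, c] + 1L
    }
  }
  rem <- sk & deg < 3
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!rem[r, c] || lab[r, c] > 0) next
    nxt <- nxt + 1L
    queue <- list(c(r, c))
    lab[r, c] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dr in -1:1) for (dc in -1:1) {
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            rem[rr, cc] && lab[rr, cc] == 0) {
          lab[rr, cc] <- nxt
          queue[[length(queue) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  nxt
}

# Thick test shapes for the skeleton pipeline.
ribbon_mask <- function(len = 100, thick = 5, pad = 8) {
  m <- matrix(FALSE, thick + 2 * pad, len + 2 * pad)
  m[pad + seq_len(thick), pad + seq_len(len)] <- TRUE
  m
}

y_mask <- function() {
  m <- matrix(FALSE, 120, 120)
  m[58:62, 10:60] <- TRUE
  for (i in 0:45) {
    m[(60 + i) + (-2:2), 60 + i] <- TRUE
    m[(60 - i) + (-2:2), 60 + i] <- TRUE
  }
  m
}

h_mask <- function() {
  m <- matrix(FALSE, 120, 100)
  m[11:110, 21:25] <- TRUE   # left bar
  m[11:110, 76:80] <- TRUE   # right bar
  m[58:62, 21:80] <- TRUE    # crossbar
  m
}

# Two-group one-way ANOVA F statistic from first principles.
oracle_anova_f <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  gm <- mean(c(g1, g2))
  ssb <- n1 * (mean(g1) - gm)^2 + n2 * (mean(g2) - gm)^2
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  (ssb / 1) / (ssw / (n1 + n2 - 2))
}
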