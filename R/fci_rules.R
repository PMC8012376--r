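# Final FCI orientation rules (Zhang's complete set, minus the
# selection-bias rules R5-R7 which cannot fire when selection bias is
# assumed absent). Marks: amat[a, b] is the mark at b on edge a~b.
# Applied repeatedly to fixpoint.

fci_orient_rules <- function(amat, sep) {
  nodes <- mg_nodes(amat)
  repeat {
    r1 <- fci_rule1(amat); amat <- r1$amat; changed <- r1$changed
    r2 <- fci_rule2(amat); amat <- r2$amat; changed <- changed || r2$changed
    r3 <- fci_rule3(amat); amat <- r3$amat; changed <- changed || r3$changed
    r4 <- fci_rule4(amat, sep); amat <- r4$amat; changed <- changed || r4$changed
    r8 <- fci_rule8(amat); amat <- r8$amat; changed <- changed || r8$changed
    r9 <- fci_rule9(amat); amat <- r9$amat; changed <- changed || r9$changed
    r10 <- fci_rule10(amat); amat <- r10$amat; changed <- changed || r10$changed
    if (!changed) break
  }
  amat
}

# R1: a *-> b o-* c, a and c nonadjacent  =>  b --> c
fci_rule1 <- function(amat) {
  changed <- FALSE
  p <- nrow(amat)
  for (b in seq_len(p)) {
    into_b <- which(amat[, b] == MARK_ARROW)
    if (!length(into_b)) next
    for (cc in mg_adjacent(amat, b)) {
      if (amat[cc, b] != MARK_CIRCLE) next
      for (a in into_b) {
        if (a == cc || mg_has_edge(amat, a, cc)) next
        amat[cc, b] <- MARK_TAIL
        amat[b, cc] <- MARK_ARROW
        changed <- TRUE
        break
      }
    }
  }
  list(amat = amat, changed = changed)
}

# R2: (a --> b *-> c or a *-> b --> c) and a *-o c  =>  a *-> c
fci_rule2 <- function(amat) {
  changed <- FALSE
  p <- nrow(amat)
  idx <- which(amat == MARK_CIRCLE, arr.ind = TRUE) # circle at c on a~c
  for (r in seq_len(nrow(idx))) {
    a <- idx[r, 1]; cc <- idx[r, 2]
    if (amat[a, cc] != MARK_CIRCLE) next # may have changed this sweep
    for (b in seq_len(p)) {
      if (b == a || b == cc) next
      chain1 <- mg_is_directed(amat, a, b) && amat[b, cc] == MARK_ARROW
      chain2 <- amat[a, b] == MARK_ARROW && mg_is_directed(amat, b, cc)
      if (chain1 || chain2) {
        amat[a, cc] <- MARK_ARROW
        changed <- TRUE
        break
      }
    }
  }
  list(amat = amat, changed = changed)
}

# R3: a *-> b <-* c, a *-o d o-* c, a and c nonadjacent, d *-o b
#     =>  d *-> b
fci_rule3 <- function(amat) {
  changed <- FALSE
  p <- nrow(amat)
  for (d in seq_len(p)) {
    for (b in mg_adjacent(amat, d)) {
      if (amat[d, b] != MARK_CIRCLE) next
      for (a in seq_len(p)) {
        if (a == d || a == b) next
        if (amat[a, b] != MARK_ARROW || amat[a, d] != MARK_CIRCLE) next
        for (cc in seq_len(p)) {
          if (cc %in% c(a, b, d)) next
          if (amat[cc, b] != MARK_ARROW || amat[cc, d] != MARK_CIRCLE) next
          if (mg_has_edge(amat, a, cc)) next
          amat[d, b] <- MARK_ARROW
          changed <- TRUE
          break
        }
        if (amat[d, b] == MARK_ARROW) break
      }
    }
  }
  list(amat = amat, changed = changed)
}

# R4 (discriminating paths): for a path <theta, ..., a, b, c> where every
# vertex between theta and b is a collider on the path and a parent of c,
# theta and c nonadjacent, and the mark at b on b~c is a circle: if b is
# in sepset(theta, c) orient b --> c, else orient a <-> b <-> c.
fci_rule4 <- function(amat, sep) {
  changed <- FALSE
  p <- nrow(amat)
  nodes <- mg_nodes(amat)
  for (b in seq_len(p)) {
    for (cc in mg_adjacent(amat, b)) {
      if (amat[cc, b] != MARK_CIRCLE) next
      # candidates a: a *-> b, a --> c
      for (a in mg_adjacent(amat, b)) {
        if (a == cc) next
        if (amat[a, b] != MARK_ARROW) next
        if (!mg_is_directed(amat, a, cc)) next
        res <- discriminating_path(amat, a, b, cc)
        if (is.null(res)) next
        theta <- res
        S <- sep[[pair_key(nodes, theta, cc)]]
        if (!is.null(S) && nodes[b] %in% S) {
          amat[cc, b] <- MARK_TAIL
          amat[b, cc] <- MARK_ARROW
        } else {
          amat[a, b] <- MARK_ARROW; amat[b, a] <- MARK_ARROW
          amat[b, cc] <- MARK_ARROW; amat[cc, b] <- MARK_ARROW
        }
        changed <- TRUE
        break
      }
    }
  }
  list(amat = amat, changed = changed)
}

# search backwards from a for the start of a discriminating path for b
# w.r.t. c; interior vertices must be colliders on the path and parents
# of c; returns the start vertex (nonadjacent to c) or NULL
discriminating_path <- function(amat, a, b, cc) {
  p <- nrow(amat)
  visited <- rep(FALSE, p)
  visited[c(a, b, cc)] <- TRUE
  # queue holds (head, predecessor-on-path-toward-b)
  queue <- list(c(a, b))
  while (length(queue)) {
    st <- queue[[1]]
    queue <- queue[-1]
    h <- st[1]; succ <- st[2]
    for (t in which(amat[, h] == MARK_ARROW)) { # t *-> h
      if (visited[t]) next
      # h must be a collider on the path: arrow at h from succ side holds
      # by construction; also need arrow into h from t (given) and
      # succ *-> ... ensured when enqueued
      if (!mg_has_edge(amat, t, cc)) {
        return(t) # found theta, nonadjacent to c
      }
      if (mg_is_directed(amat, t, cc) && amat[succ, h] == MARK_ARROW &&
          amat[h, t] == MARK_ARROW) {
        visited[t] <- TRUE
        queue <- c(queue, list(c(t, h)))
      }
    }
  }
  NULL
}

# R8: a --> b --> c and a o-> c  =>  a --> c (tail at a)
fci_rule8 <- function(amat) {
  changed <- FALSE
  idx <- which(amat == MARK_ARROW & t(amat) == MARK_CIRCLE, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    a <- idx[r, 1]; cc <- idx[r, 2]
    for (b in mg_children(amat, a)) {
      if (b != cc && mg_is_directed(amat, b, cc)) {
        amat[cc, a] <- MARK_TAIL
        changed <- TRUE
        break
      }
    }
  }
  list(amat = amat, changed = changed)
}

# possibly-directed edge from u to v: no arrow back at u, no tail at v
pd_edge <- function(amat, u, v) {
  amat[u, v] != 0L && amat[v, u] != MARK_ARROW && amat[u, v] != MARK_TAIL
}

# is there an uncovered possibly-directed path from a to c whose first
# vertex after a is not adjacent to c (and is not c itself)?
uncovered_pd_path_exists <- function(amat, a, cc, first = NULL) {
  p <- nrow(amat)
  starts <- if (is.null(first)) {
    Filter(function(b) b != cc && !mg_has_edge(amat, b, cc) &&
             pd_edge(amat, a, b), seq_len(p))
  } else {
    if (pd_edge(amat, a, first)) list(first) else list()
  }
  for (b in starts) {
    if (ucpd_dfs(amat, a, b, cc, visited = c(a, b))) return(TRUE)
  }
  FALSE
}

ucpd_dfs <- function(amat, prev, cur, target, visited) {
  if (cur == target) return(TRUE)
  for (nxt in which(amat[cur, ] != 0L)) {
    if (nxt %in% visited) next
    if (!pd_edge(amat, cur, nxt)) next
    if (mg_has_edge(amat, prev, nxt)) next # uncovered condition
    if (ucpd_dfs(amat, cur, nxt, target, c(visited, nxt))) return(TRUE)
  }
  FALSE
}

# R9: a o-> c and an uncovered pd path <a, b, ..., c> with b nonadjacent
# to c  =>  a --> c
fci_rule9 <- function(amat) {
  changed <- FALSE
  idx <- which(amat == MARK_ARROW & t(amat) == MARK_CIRCLE, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    a <- idx[r, 1]; cc <- idx[r, 2]
    if (uncovered_pd_path_exists(amat, a, cc)) {
      amat[cc, a] <- MARK_TAIL
      changed <- TRUE
    }
  }
  list(amat = amat, changed = changed)
}

# R10: a o-> c, b --> c <-- d, uncovered pd paths from a to b and from a
# to d whose first vertices m != n are nonadjacent  =>  a --> c
fci_rule10 <- function(amat) {
  changed <- FALSE
  p <- nrow(amat)
  idx <- which(amat == MARK_ARROW & t(amat) == MARK_CIRCLE, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    a <- idx[r, 1]; cc <- idx[r, 2]
    pa_c <- setdiff(mg_parents(amat, cc), a)
    if (length(pa_c) < 2) next
    done <- FALSE
    for (b in pa_c) {
      for (d in pa_c) {
        if (done || b >= d) next
        for (m in which(amat[a, ] != 0L)) {
          for (n in which(amat[a, ] != 0L)) {
            if (m == n || mg_has_edge(amat, m, n)) next
            ok_m <- (m == b && pd_edge(amat, a, b)) ||
              first_step_ucpd(amat, a, m, b)
            ok_n <- (n == d && pd_edge(amat, a, d)) ||
              first_step_ucpd(amat, a, n, d)
            if (ok_m && ok_n) {
              amat[cc, a] <- MARK_TAIL
              changed <- TRUE
              done <- TRUE
              break
            }
          }
          if (done) break
        }
      }
    }
  }
  list(amat = amat, changed = changed)
}

first_step_ucpd <- function(amat, a, first, target) {
  if (!pd_edge(amat, a, first)) return(FALSE)
  if (first == target) return(TRUE)
  ucpd_dfs(amat, a, first, target, visited = c(a, first))
}
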