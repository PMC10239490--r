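# Independent oracles.
#
# lagrangian_eom(): symbolic Lagrangian dynamics of a planar tree, derived
# by base-R symbolic differentiation (D()) of the kinetic and potential
# energy built from the segment geometry.  This is a derivation path fully
# independent of the package's Newton-Euler-style engines: EOM_j =
# d/dt(dT/dqdot_j) - dT/dq_j + dV/dq_j, with the total time derivative
# expanded over (q, qd, qdd).

lagrangian_eom_builder <- function(bundle) {
  st <- bundle$planar
  nq <- bundle$layout$n_q
  n <- st$n_seg
  qs <- paste0("q", seq_len(nq))
  qds <- paste0("qd", seq_len(nq))
  qdds <- paste0("qdd", seq_len(nq))
  num <- function(x) as.numeric(x)
  add <- function(a, b) call("+", a, b)
  mul <- function(a, b) call("*", a, b)
  csum <- function(lst) Reduce(add, lst)

  th <- vector("list", n); Px <- th; Pz <- th
  for (i in seq_len(n)) {
    p <- st$parent[i]
    if (p == 0L) {
      rq <- st$rot_q[i]
      th[[i]] <- mul(as.name(qs[rq]), num(st$sign[i]))
      Px[[i]] <- add(num(st$org_x[i]), as.name(qs[rq - 2L]))
      Pz[[i]] <- add(num(st$org_z[i]), as.name(qs[rq - 1L]))
    } else {
      thp <- th[[p]]
      wx <- add(mul(call("cos", thp), num(st$org_x[i])),
                mul(call("sin", thp), num(st$org_z[i])))
      wz <- add(mul(num(-st$org_x[i]), call("sin", thp)),
                mul(call("cos", thp), num(st$org_z[i])))
      Px[[i]] <- add(Px[[p]], wx)
      Pz[[i]] <- add(Pz[[p]], wz)
      th[[i]] <- add(th[[p]], mul(as.name(qs[st$rot_q[i]]), num(st$sign[i])))
    }
  }
  Tterms <- list(); Vterms <- list()
  for (i in seq_len(n)) {
    thi <- th[[i]]
    cx <- add(Px[[i]], add(mul(call("cos", thi), num(st$com_x[i])),
                           mul(call("sin", thi), num(st$com_z[i]))))
    cz <- add(Pz[[i]], add(mul(num(-st$com_x[i]), call("sin", thi)),
                           mul(call("cos", thi), num(st$com_z[i]))))
    vx <- csum(lapply(seq_len(nq), function(j)
      mul(D(cx, qs[j]), as.name(qds[j]))))
    vz <- csum(lapply(seq_len(nq), function(j)
      mul(D(cz, qs[j]), as.name(qds[j]))))
    w <- csum(lapply(seq_len(nq), function(j)
      mul(D(thi, qs[j]), as.name(qds[j]))))
    Tterms[[i]] <- add(mul(num(0.5 * st$mass[i]),
                           add(call("^", vx, 2), call("^", vz, 2))),
                       mul(num(0.5 * st$Iy[i]), call("^", w, 2)))
    Vterms[[i]] <- mul(num(st$mass[i] * 9.81), cz)
  }
  Texpr <- csum(Tterms); Vexpr <- csum(Vterms)
  eoms <- vector("list", nq)
  for (j in seq_len(nq)) {
    Aj <- D(Texpr, qds[j])
    ddt <- csum(c(
      lapply(seq_len(nq), function(k) mul(D(Aj, qs[k]), as.name(qds[k]))),
      lapply(seq_len(nq), function(k) mul(D(Aj, qds[k]), as.name(qdds[k])))))
    eoms[[j]] <- add(add(ddt, mul(num(-1), D(Texpr, qs[j]))), D(Vexpr, qs[j]))
  }
  function(q, qd, qdd) {
    env <- new.env(parent = baseenv())
    for (j in seq_len(nq)) {
      assign(qs[j], q[j], env); assign(qds[j], qd[j], env)
      assign(qdds[j], qdd[j], env)
    }
    vapply(eoms, eval, 0, envir = env)
  }
}

lagrangian_eom <- function() {
  cached("lagrangian_fun", lagrangian_eom_builder(bare_planar_bundle()))
}

# homogeneous-transform product oracle for a chain of revolute-y joints
# (independent of forward_kinematics' recursion)
chain_fk_oracle <- function(origins, angles) {
  H <- diag(4)
  out <- matrix(0, 3, length(angles))
  for (i in seq_along(angles)) {
    Ti <- diag(4)
    Ti[1:3, 4] <- origins[[i]]
    a <- angles[i]
    Ti[1:3, 1:3] <- matrix(c(cos(a), 0, -sin(a), 0, 1, 0,
                             sin(a), 0, cos(a)), 3, 3)
    H <- H %*% Ti
    out[, i] <- H[1:3, 4]
  }
  out
}
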