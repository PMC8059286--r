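# Independent transcriptions of the published prediction equations, used as
# oracles against the package's stepwise vergence implementation. These are
# deliberately written from the formulas' printed closed forms (the
# single-quotient refraction expressions, and Hoffer's solved power
# equation), sharing no code with the package.

# SRK/T predicted spectacle refraction (Retzlaff 1990 + erratum), mm units
oracle_srkt <- function(a_const, al, km, power, vertex = 12) {
  r <- 337.5 / km
  na <- 1.336
  ncm1 <- 1.333 - 1
  acd_const <- 0.62467 * a_const - 68.747
  offset <- acd_const - 3.336
  lcor <- ifelse(al <= 24.2, al, -3.446 + 1.716 * al - 0.0237 * al^2)
  cw <- -5.41 + 0.58412 * lcor + 0.098 * km
  h <- r - sqrt(pmax(0, r^2 - cw^2 / 4))
  c1 <- h + offset
  lopt <- al + 0.65696 - 0.02029 * al
  num <- 1000 * na * (na * r - ncm1 * lopt) -
    power * (lopt - c1) * (na * r - ncm1 * c1)
  den <- na * (vertex * (na * r - ncm1 * lopt) + lopt * r) -
    0.001 * power * (lopt - c1) * (vertex * (na * r - ncm1 * c1) + c1 * r)
  num / den
}

# Holladay 1 predicted spectacle refraction (Holladay 1988), mm units
oracle_holladay1 <- function(sf, al, km, power, vertex = 12) {
  r <- 337.5 / km
  na <- 1.336
  ncm1 <- 4 / 3 - 1
  rag <- pmax(r, 7)
  ag <- pmin(12.5 * al / 23.45, 13.5)
  aacd <- 0.56 + rag - sqrt(pmax(0, rag^2 - ag^2 / 4))
  c1 <- aacd + sf
  lopt <- al + 0.2
  num <- 1000 * na * (na * r - ncm1 * lopt) -
    power * (lopt - c1) * (na * r - ncm1 * c1)
  den <- na * (vertex * (na * r - ncm1 * lopt) + lopt * r) -
    0.001 * power * (lopt - c1) * (vertex * (na * r - ncm1 * c1) + c1 * r)
  num / den
}

# Hoffer Q (Hoffer 1993 + errata): invert the published power equation
# P = 1336/(AL - C - 0.05) - 1.336/(1.336/(K + Rc) - (C + 0.05)/1000)
# for the corneal-plane refraction Rc, then move to the spectacle plane.
oracle_hofferq <- function(pacd, al, km, power, vertex = 12) {
  tan_deg <- function(x) tan(x * pi / 180)
  alc <- pmin(pmax(al, 18.5), 31)
  m <- ifelse(al <= 23, 1, -1)
  g <- ifelse(al <= 23, 28, 23.5)
  c1 <- pacd + 0.3 * (alc - 23.5) + tan_deg(km)^2 +
    0.1 * m * (23.5 - alc)^2 * tan_deg(0.1 * (g - alc)^2) - 0.99166
  lhs <- 1336 / (al - c1 - 0.05) - power            # = 1.336/(1.336/(K+Rc) - (C+.05)/1000)
  inner <- (c1 + 0.05) / 1000 + 1.336 / lhs          # = 1.336/(K+Rc)
  rc <- 1.336 / inner - km
  rc / (1 + (vertex / 1000) * rc)
}

# Haigis (Haigis 2000): published vergence chain with d = a0 + a1 ACD + a2 AL
# and corneal power from the radius with index 1.3315; meters throughout.
oracle_haigis <- function(a0, a1, a2, acd, al, km, power, vertex = 12) {
  r <- 337.5 / km
  dc <- (1.3315 - 1) / (r / 1000)
  d <- (a0 + a1 * acd + a2 * al) / 1000
  l <- al / 1000
  n <- 1.336
  z <- n / (d + n / (n / (l - d) - power))           # corneal vergence
  rc <- z - dc
  rc / (1 + (vertex / 1000) * rc)
}

# Full enumeration of the two-sided Mann-Whitney / rank-sum p-value:
# every C(n+m, n) relabeling of the pooled sample.
enum_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  m <- length(y)
  u_of <- function(idx) {
    sum(rank(pooled)[idx]) - n * (n + 1) / 2
  }
  u_obs <- u_of(seq_len(n))
  dev_obs <- abs(u_obs - n * m / 2)
  combs <- utils::combn(length(pooled), n)
  devs <- apply(combs, 2, function(idx) abs(u_of(idx) - n * m / 2))
  mean(devs >= dev_obs - 1e-12)
}

# Full enumeration of the two-sided one-sample signed-rank p-value over all
# 2^n sign patterns (assumes no zeros).
enum_signedrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  ev <- n * (n + 1) / 4
  dev_obs <- abs(v_obs - ev)
  signs <- expand.grid(rep(list(c(FALSE, TRUE)), n))
  devs <- apply(signs, 1, function(s) abs(sum(r[unlist(s)]) - ev))
  mean(devs >= dev_obs - 1e-12)
}
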