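// Hot loop of the PCHB excitation generator.  One call proposes a batch of
// excitations from parent determinants held as alpha/beta bit masks, using
// R's global RNG stream (so runs are reproducible from set.seed()).
//
// Spin-orbital convention: 1..n alpha block, n+1..2n beta block, ascending
// spatial index; fermionic phases count occupied spin orbitals between the
// excitation endpoints in that fixed order.

#include <Rcpp.h>
using namespace Rcpp;

static inline int spat(int s, int n) { return s > n ? s - n : s; }

// [[Rcpp::export]]
List cpp_pchb_propose(List tables,
                      IntegerVector amask, IntegerVector bmask,
                      IntegerVector isg, IntegerMatrix occ,
                      IntegerVector pidx, int kind_force,
                      IntegerMatrix ra, IntegerMatrix rb) {
  const int n = as<int>(tables["n_orb"]);
  const int P = as<int>(tables["P"]);
  const int M = P;
  NumericVector prob = tables["prob"];
  IntegerVector alias = tables["alias"];
  NumericVector pnorm = tables["pnorm"];
  NumericMatrix wtot = tables["wtot"];
  IntegerVector pairA = tables["pairA"], pairB = tables["pairB"];
  IntegerMatrix prank = tables["pair_rank"];
  IntegerMatrix smask = tables["smask"];
  IntegerVector space_of = tables["space_of"];
  const int full_mask = as<int>(tables["full_mask"]);
  const double p_double = as<double>(tables["p_double"]);
  NumericMatrix h = tables["h"];
  NumericVector g = tables["g"];
  const int nel = occ.ncol();
  const int nat = pidx.size();
  const double n2 = (double)n * n, n3 = (double)n * n * n;

  IntegerVector kind(nat), reason(nat), outI(nat, NA_INTEGER),
      outJ(nat, NA_INTEGER), outA(nat, NA_INTEGER), outB(nat, NA_INTEGER),
      child_a(nat), child_b(nat), phase(nat);
  LogicalVector valid(nat);
  NumericVector pgen(nat), hmat(nat);

  auto occ_test = [&](int row, int s) -> bool {
    if (s <= n) return (amask[row] >> (s - 1)) & 1;
    return (bmask[row] >> (s - n - 1)) & 1;
  };
  auto between = [&](int am, int bm, int p, int q) -> int {
    int lo = p < q ? p : q, hi = p < q ? q : p;
    return __builtin_popcount(am & ra(lo - 1, hi - 1)) +
           __builtin_popcount(bm & rb(lo - 1, hi - 1));
  };
  auto gval = [&](int a, int i, int b, int j) -> double {
    return g[(a - 1) + n * (i - 1) + n2 * (b - 1) + n3 * (j - 1)];
  };

  for (int t = 0; t < nat; ++t) {
    const int p = pidx[t] - 1;
    bool isd;
    if (kind_force == 1) isd = true;
    else if (kind_force == 2) isd = false;
    else isd = unif_rand() < p_double;
    kind[t] = isd ? 1 : 2;

    if (isd) {
      int r1 = 1 + (int)(unif_rand() * nel); if (r1 > nel) r1 = nel;
      int r2 = 1 + (int)(unif_rand() * (nel - 1)); if (r2 > nel - 1) r2 = nel - 1;
      if (r2 >= r1) r2++;
      int I = occ(p, r1 - 1), J = occ(p, r2 - 1);
      if (I > J) std::swap(I, J);
      const int pr = prank(I - 1, J - 1);
      const int sg = isg[p];
      outI[t] = I; outJ[t] = J;
      const double wt = wtot(pr - 1, sg - 1);
      if (wt <= 0) { reason[t] = 3; continue; }
      int slot = 1 + (int)(unif_rand() * M); if (slot > M) slot = M;
      const R_xlen_t base = (R_xlen_t)M * (pr - 1) + (R_xlen_t)M * P * (sg - 1);
      const double u = unif_rand();
      const int hp = (u < prob[base + slot - 1]) ? slot : alias[base + slot - 1];
      const int A = pairA[hp - 1], B = pairB[hp - 1];
      outA[t] = A; outB[t] = B;
      pgen[t] = p_double * 2.0 / (nel * (nel - 1.0)) * pnorm[base + hp - 1];
      if (occ_test(p, A) || occ_test(p, B)) { reason[t] = 1; continue; }
      valid[t] = true;
      const int i0 = spat(I, n), j0 = spat(J, n), a0 = spat(A, n), b0 = spat(B, n);
      const bool sI = I <= n, sJ = J <= n, sA = A <= n, sB = B <= n;
      double t1 = (sA == sI && sB == sJ) ? gval(a0, i0, b0, j0) : 0.0;
      double t2 = (sA == sJ && sB == sI) ? gval(a0, j0, b0, i0) : 0.0;
      const int am = amask[p], bm = bmask[p];
      int ph = between(am, bm, I, A);
      const int lo = std::min(J, B), hi = std::max(J, B);
      ph += between(am, bm, J, B) - ((I > lo && I < hi) ? 1 : 0) +
            ((A > lo && A < hi) ? 1 : 0);
      const int phv = (ph % 2) ? -1 : 1;
      phase[t] = phv;
      hmat[t] = phv * (t1 - t2);
      int ca = am, cb = bm;
      if (sI) ca -= 1 << (i0 - 1); else cb -= 1 << (i0 - 1);
      if (sJ) ca -= 1 << (j0 - 1); else cb -= 1 << (j0 - 1);
      if (sA) ca += 1 << (a0 - 1); else cb += 1 << (a0 - 1);
      if (sB) ca += 1 << (b0 - 1); else cb += 1 << (b0 - 1);
      child_a[t] = ca; child_b[t] = cb;
    } else {
      int r = 1 + (int)(unif_rand() * nel); if (r > nel) r = nel;
      const int I = occ(p, r - 1);
      const bool alf = I <= n;
      const int i0 = alf ? I : I - n;
      const int sg = isg[p];
      const int sm = smask(space_of[i0 - 1] - 1, sg - 1);
      const int occ_sigma = alf ? amask[p] : bmask[p];
      const int cand = sm & (~occ_sigma) & full_mask;
      const int Ntil = __builtin_popcount(cand);
      outI[t] = I;
      if (Ntil == 0) { reason[t] = 2; continue; }
      int rr = 1 + (int)(unif_rand() * Ntil); if (rr > Ntil) rr = Ntil;
      int a0 = 0, cnt = 0;
      for (int b = 1; b <= n; ++b) {
        if ((cand >> (b - 1)) & 1) {
          if (++cnt == rr) { a0 = b; break; }
        }
      }
      const int A = alf ? a0 : a0 + n;
      outA[t] = A;
      valid[t] = true;
      pgen[t] = (1.0 - p_double) / ((double)nel * Ntil);
      double val = h(a0 - 1, i0 - 1);
      for (int e = 0; e < nel; ++e) {
        const int Pso = occ(p, e);
        const int p0 = spat(Pso, n);
        val += gval(a0, i0, p0, p0);
        if ((Pso <= n) == alf) val -= gval(a0, p0, p0, i0);
      }
      const int am = amask[p], bm = bmask[p];
      const int phv = (between(am, bm, I, A) % 2) ? -1 : 1;
      phase[t] = phv;
      hmat[t] = phv * val;
      const int delta = (1 << (a0 - 1)) - (1 << (i0 - 1));
      child_a[t] = am + (alf ? delta : 0);
      child_b[t] = bm + (alf ? 0 : delta);
    }
  }
  return List::create(_["parent"] = pidx, _["kind"] = kind,
                      _["valid"] = valid, _["reason"] = reason,
                      _["I"] = outI, _["J"] = outJ, _["A"] = outA,
                      _["B"] = outB, _["child_a"] = child_a,
                      _["child_b"] = child_b, _["pgen"] = pgen,
                      _["hmat"] = hmat, _["phase"] = phase);
}
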