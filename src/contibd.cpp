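#include <Rcpp.h>
using namespace Rcpp;

// Continuous-time IBD process on the reduced inheritance-vector space:
// nbits meioses, each flipping independently at 0.01 crossovers per cM
// (Haldane). States are integers 0..2^nbits-1; ibd1[s] says whether state
// s maps to IBD1. All exact computations use uniformization: conditional
// on k crossovers (Poisson), each crossover flips one uniformly chosen
// bit.

// Simulate the continuous IBD process for one chromosome, nrep
// independent replicates, returning observed IBD segments (runs of
// constant X). Uses R's RNG so results are governed by set.seed().
// [[Rcpp::export]]
List cpp_sim_segments(LogicalVector ibd1, int nbits, double L, int nrep) {
  const int nv = 1 << nbits;
  const double rate = 0.01 * nbits;
  std::vector<int> rep_out, state_out;
  std::vector<double> start_out, end_out;
  for (int i = 0; i < nrep; ++i) {
    int s = (int)(unif_rand() * nv);
    if (s >= nv) s = nv - 1;
    int x = ibd1[s] ? 1 : 0;
    double pos = 0.0, segstart = 0.0;
    if (rate > 0) {
      while (true) {
        pos += exp_rand() / rate;
        if (pos >= L) break;
        int j = (int)(unif_rand() * nbits);
        if (j >= nbits) j = nbits - 1;
        s ^= (1 << j);
        int nx = ibd1[s] ? 1 : 0;
        if (nx != x) {
          rep_out.push_back(i + 1);
          start_out.push_back(segstart);
          end_out.push_back(pos);
          state_out.push_back(x);
          segstart = pos;
          x = nx;
        }
      }
    }
    rep_out.push_back(i + 1);
    start_out.push_back(segstart);
    end_out.push_back(L);
    state_out.push_back(x);
  }
  return List::create(_["rep"] = wrap(rep_out), _["start"] = wrap(start_out),
                      _["end"] = wrap(end_out), _["state"] = wrap(state_out));
}

// Genome-level summary simulation: number of IBD1 segments and total IBD1
// length per replicate, across a whole map, without storing segments.
// [[Rcpp::export]]
List cpp_sim_summary(LogicalVector ibd1, int nbits, NumericVector lengths,
                     int nrep) {
  const int nv = 1 << nbits;
  const double rate = 0.01 * nbits;
  IntegerVector nseg(nrep);
  NumericVector total(nrep);
  for (int i = 0; i < nrep; ++i) {
    int count = 0;
    double tot = 0.0;
    for (int c = 0; c < lengths.size(); ++c) {
      const double L = lengths[c];
      int s = (int)(unif_rand() * nv);
      if (s >= nv) s = nv - 1;
      int x = ibd1[s] ? 1 : 0;
      if (x == 1) ++count;
      double pos = 0.0, segstart = 0.0;
      while (true) {
        double nxt = pos + exp_rand() / rate;
        if (nxt >= L) {
          if (x == 1) tot += L - segstart;
          break;
        }
        pos = nxt;
        int j = (int)(unif_rand() * nbits);
        if (j >= nbits) j = nbits - 1;
        s ^= (1 << j);
        int nx = ibd1[s] ? 1 : 0;
        if (nx != x) {
          if (x == 1) tot += pos - segstart;
          else ++count;
          segstart = pos;
          x = nx;
        }
      }
    }
    nseg[i] = count;
    total[i] = tot;
  }
  return List::create(_["nseg"] = nseg, _["total"] = total);
}

// One uniformized crossover step restricted to the class S_x:
// out[v] = (1/nbits) * sum_j in[v ^ bit_j] for v with class(v) == x.
static void step_restricted(const std::vector<double>& in,
                            std::vector<double>& out,
                            const LogicalVector& ibd1, int nbits, int x) {
  const int nv = 1 << nbits;
  const double inv = 1.0 / nbits;
  for (int v = 0; v < nv; ++v) {
    if ((ibd1[v] ? 1 : 0) != x) { out[v] = 0.0; continue; }
    double acc = 0.0;
    for (int j = 0; j < nbits; ++j) acc += in[v ^ (1 << j)];
    out[v] = acc * inv;
  }
}

// Exact log-likelihood of continuously observed IBD segments for a batch
// of genomes. Segments are laid out contiguously per replicate (offsets
// rep_off, 0-based, length nrep+1), ordered by chromosome within each
// replicate. Within a segment of state x and length len, the hidden chain
// must stay inside S_x (Poisson-conditioned forward recursion, truncation
// error <= eps per segment); interior segment boundaries contribute the
// exit intensity (0.01 per crossing Hamming-1 neighbour) as a density in
// the breakpoint position; the last segment of each chromosome only
// contributes the staying probability. Returns natural-log likelihoods;
// -Inf flags an observation impossible under the hypothesis.
// [[Rcpp::export]]
NumericVector cpp_loglik_many(LogicalVector ibd1, int nbits,
                              IntegerVector rep_off, IntegerVector seg_chrom,
                              NumericVector seg_len, IntegerVector seg_state,
                              double eps) {
  const int nv = 1 << nbits;
  const int nrep = rep_off.size() - 1;
  NumericVector out(nrep);
  std::vector<double> alpha(nv), cur(nv), nxt(nv), acc(nv);

  for (int i = 0; i < nrep; ++i) {
    double logl = 0.0;
    bool dead = false;
    int lo = rep_off[i], hi = rep_off[i + 1];
    int k = lo;
    while (k < hi && !dead) {
      // one chromosome = contiguous run with the same chromosome id
      int chrom = seg_chrom[k];
      int cend = k;
      while (cend < hi && seg_chrom[cend] == chrom) ++cend;
      // init: uniform prior restricted to the first segment's class
      int x0 = seg_state[k];
      for (int v = 0; v < nv; ++v)
        alpha[v] = ((ibd1[v] ? 1 : 0) == x0) ? 1.0 / nv : 0.0;
      for (int si = k; si < cend && !dead; ++si) {
        int x = seg_state[si];
        double len = seg_len[si];
        double lambda = 0.01 * nbits * len;
        // staying operator: sum_k Pois(k; lambda) * P_x^k
        int kmax = (int)R::qpois(1.0 - eps, lambda, 1, 0);
        for (int v = 0; v < nv; ++v) {
          double a = ((ibd1[v] ? 1 : 0) == x) ? alpha[v] : 0.0;
          cur[v] = a;
          acc[v] = R::dpois(0, lambda, 0) * a;
        }
        for (int kk = 1; kk <= kmax; ++kk) {
          step_restricted(cur, nxt, ibd1, nbits, x);
          std::swap(cur, nxt);
          double w = R::dpois(kk, lambda, 0);
          for (int v = 0; v < nv; ++v) acc[v] += w * cur[v];
        }
        if (si < cend - 1) {
          // interior boundary: exit flux into the complementary class
          for (int v = 0; v < nv; ++v) {
            if ((ibd1[v] ? 1 : 0) == x) { alpha[v] = 0.0; continue; }
            double flux = 0.0;
            for (int j = 0; j < nbits; ++j) {
              int u = v ^ (1 << j);
              if ((ibd1[u] ? 1 : 0) == x) flux += acc[u];
            }
            alpha[v] = 0.01 * flux;
          }
        } else {
          for (int v = 0; v < nv; ++v) alpha[v] = acc[v];
        }
        double s = 0.0;
        for (int v = 0; v < nv; ++v) s += alpha[v];
        if (s <= 0.0 || !R_finite(s)) {
          dead = true;
        } else {
          logl += std::log(s);
          for (int v = 0; v < nv; ++v) alpha[v] /= s;
        }
      }
      k = cend;
    }
    out[i] = dead ? R_NegInf : logl;
  }
  return out;
}

// Stationary count of ordered Hamming-1 pairs crossing from IBD0 to IBD1
// (used for the expected segment count via the up-crossing flux).
// [[Rcpp::export]]
double cpp_crossing_pairs(LogicalVector ibd1, int nbits) {
  const int nv = 1 << nbits;
  double n = 0.0;
  for (int v = 0; v < nv; ++v) {
    if (ibd1[v]) continue;
    for (int j = 0; j < nbits; ++j)
      if (ibd1[v ^ (1 << j)]) n += 1.0;
  }
  return n;
}

// Hamming-distance tabulation over V1 x V1 (for the two-locus IBD
// probability); returns counts c[h], h = 0..nbits.
// [[Rcpp::export]]
NumericVector cpp_hamming_counts(IntegerVector v1, int nbits) {
  NumericVector counts(nbits + 1);
  const int n = v1.size();
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      int x = v1[i] ^ v1[j];
      int h = 0;
      while (x) { h += x & 1; x >>= 1; }
      counts[h] += 1.0;
    }
  }
  return counts;
}
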