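// Forward Wright-Fisher simulator of a haploid panel with an optional
// selective sweep at a focal position.
//
// Discrete generations, multiplicative fitness 1+s for carriers of the
// focal allele, single-crossover recombination at rate rec*L per meiosis,
// and (approximately) infinite-sites mutation at uniform integer positions
// (collisions with currently occupied positions are redrawn). Uses R's RNG
// throughout so set.seed() on the R side gives full determinism.
//
// The population lives in a flat N x cap byte buffer (row per individual)
// that is double-buffered between generations; fixed and lost columns are
// compacted away every few generations (they are inert in between).

#include <Rcpp.h>
#include <vector>
#include <set>
#include <cstring>
#include <algorithm>
using namespace Rcpp;

struct Pop {
  int N;
  int L;
  int S;                    // live columns
  int cap;                  // column capacity (row stride)
  std::vector<unsigned char> g;  // N * cap, row-major
  std::vector<int> pos;     // 1-based bp per column, size S
  std::set<int> occupied;   // positions currently in use
  int focal_col;            // -1 if absent

  unsigned char *row(int k) { return &g[(size_t)k * cap]; }

  void reserve_cap(int need) {
    if (need <= cap) return;
    int newcap = std::max(need, cap * 2 + 64);
    std::vector<unsigned char> ng((size_t)N * newcap, 0);
    for (int k = 0; k < N; ++k)
      std::memcpy(&ng[(size_t)k * newcap], row(k), S);
    g.swap(ng);
    cap = newcap;
  }

  // drop fixed and lost columns; returns pre-compaction focal count
  void compact(int *focal_count = 0) {
    std::vector<int> counts(S, 0);
    for (int k = 0; k < N; ++k) {
      const unsigned char *r = row(k);
      for (int c = 0; c < S; ++c) counts[c] += r[c];
    }
    if (focal_count && focal_col >= 0) *focal_count = counts[focal_col];
    std::vector<int> keep;
    keep.reserve(S);
    int new_focal = -1;
    for (int c = 0; c < S; ++c) {
      if (counts[c] > 0 && counts[c] < N) {
        if (c == focal_col) new_focal = (int)keep.size();
        keep.push_back(c);
      } else {
        occupied.erase(pos[c]);
      }
    }
    if ((int)keep.size() != S) {
      for (int k = 0; k < N; ++k) {
        unsigned char *r = row(k);
        for (size_t c = 0; c < keep.size(); ++c) r[c] = r[keep[c]];
        std::memset(r + keep.size(), 0, S - keep.size());
      }
      std::vector<int> np(keep.size());
      for (size_t c = 0; c < keep.size(); ++c) np[c] = pos[keep[c]];
      pos.swap(np);
      S = (int)keep.size();
    }
    focal_col = new_focal;
  }

  int focal_count() const {
    if (focal_col < 0) return -1;
    int cnt = 0;
    for (int k = 0; k < N; ++k) cnt += g[(size_t)k * cap + focal_col];
    return cnt;
  }
};

static int pick_parent(Pop &p, double s) {
  if (p.focal_col < 0 || s <= 0.0)
    return (int)(unif_rand() * p.N) % p.N;
  for (;;) {  // carriers accepted with prob 1, others 1/(1+s)
    int i = (int)(unif_rand() * p.N) % p.N;
    if (p.row(i)[p.focal_col]) return i;
    if (unif_rand() < 1.0 / (1.0 + s)) return i;
  }
}

// one generation: p -> scratch, then swap buffers
static void next_generation(Pop &p, std::vector<unsigned char> &scratch,
                            double mu, double rec, double s) {
  const int N = p.N, L = p.L;
  const double rec_tot = rec * (double)L;  // mean crossovers per meiosis
  const double mu_tot = mu * (double)L;
  // mutations are drawn up-front so capacity can be sized before copying
  std::vector<std::pair<int,int> > muts;  // (column, individual)
  std::vector<int> parent1(N);
  for (int k = 0; k < N; ++k) parent1[k] = pick_parent(p, s);
  int S_new = p.S;
  for (int k = 0; k < N; ++k) {
    int nm = (int) R::rpois(mu_tot);
    for (int m = 0; m < nm; ++m) {
      int q, guard = 0;
      do {
        q = 1 + (int)(unif_rand() * (double)L) % L;
      } while (p.occupied.count(q) && ++guard < 1000);
      if (p.occupied.count(q)) continue;  // region saturated; drop
      p.occupied.insert(q);
      p.pos.push_back(q);
      muts.push_back(std::make_pair(S_new++, k));
    }
  }
  p.reserve_cap(S_new);
  if ((int)scratch.size() < N * p.cap) scratch.assign((size_t)N * p.cap, 0);
  for (int k = 0; k < N; ++k) {
    unsigned char *child = &scratch[(size_t)k * p.cap];
    std::memcpy(child, p.row(parent1[k]), p.S);
    int ncx = (p.S > 0 && rec_tot > 0) ? (int) R::rpois(rec_tot) : 0;
    if (ncx > 0) {
      // Poisson-many crossovers between the two parental haplotypes:
      // the child alternates parental origin at each breakpoint
      int p2 = pick_parent(p, s);
      const unsigned char *r2 = p.row(p2);
      std::vector<double> cx(ncx);
      for (int m = 0; m < ncx; ++m) cx[m] = unif_rand() * (double)L;
      std::sort(cx.begin(), cx.end());
      for (int c = 0; c < p.S; ++c) {
        int seg = (int)(std::upper_bound(cx.begin(), cx.end(),
                                         (double)p.pos[c]) - cx.begin());
        if (seg % 2 == 1) child[c] = r2[c];
      }
    }
    std::memset(child + p.S, 0, S_new - p.S);
  }
  for (size_t m = 0; m < muts.size(); ++m)
    scratch[(size_t)muts[m].second * p.cap + muts[m].first] = 1;
  p.g.swap(scratch);
  p.S = S_new;
}

// [[Rcpp::export]]
List wf_sim_cpp(int N, int L, double mu, double rec, double s,
                int focal_pos, int n_sample, int burn_in, int post_fix,
                int max_restarts, int max_sweep_gens, double fix_freq) {
  if (N < 2) stop("population size N must be >= 2");
  if (n_sample > N) stop("n_sample (%d) exceeds population size (%d)",
                         n_sample, N);
  const int COMPACT_EVERY = 8;
  Pop p;
  p.N = N; p.L = L; p.S = 0; p.cap = 64;
  p.g.assign((size_t)N * p.cap, 0);
  p.focal_col = -1;
  std::vector<unsigned char> scratch;

  for (int g = 0; g < burn_in; ++g) {
    next_generation(p, scratch, mu, rec, 0.0);
    if (g % COMPACT_EVERY == 0) p.compact();
  }
  p.compact();

  std::vector<double> traj;
  int fixation_gen = NA_INTEGER;
  int n_restarts = 0;

  if (s > 0.0) {
    // equilibrium snapshot to restart from if the focal allele is lost
    std::vector<unsigned char> save_g = p.g;
    std::vector<int> save_pos = p.pos;
    std::set<int> save_occ = p.occupied;
    int save_S = p.S, save_cap = p.cap;
    bool fixed = false;
    for (int attempt = 0; attempt <= max_restarts && !fixed; ++attempt) {
      if (attempt > 0) {
        p.g = save_g; p.pos = save_pos; p.occupied = save_occ;
        p.S = save_S; p.cap = save_cap; p.focal_col = -1;
        ++n_restarts;
      }
      traj.clear();
      int fpos = focal_pos;
      while (p.occupied.count(fpos)) ++fpos;
      p.reserve_cap(p.S + 1);
      int carrier = (int)(unif_rand() * N) % N;
      for (int k = 0; k < N; ++k) p.row(k)[p.S] = (k == carrier);
      p.pos.push_back(fpos);
      p.occupied.insert(fpos);
      p.focal_col = p.S;
      p.S += 1;
      traj.push_back(1.0 / (double)N);
      for (int g = 1; g <= max_sweep_gens; ++g) {
        next_generation(p, scratch, mu, rec, s);
        int cnt = p.focal_count();
        traj.push_back((double)cnt / (double)N);
        if (g % COMPACT_EVERY == 0 && cnt > 0 && cnt < N) p.compact();
        if (cnt == 0) break;                         // lost: restart
        if ((double)cnt >= fix_freq * (double)N) {
          fixed = true; fixation_gen = g; break;
        }
      }
    }
    if (!fixed)
      stop("focal allele failed to fix within %d restarts", max_restarts);
    p.compact();
    for (int g = 0; g < post_fix; ++g) {
      next_generation(p, scratch, mu, rec, 0.0);
      if (g % COMPACT_EVERY == 0) p.compact();
    }
    p.compact();
  }

  // sample n_sample distinct individuals (partial Fisher-Yates)
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  for (int i = 0; i < n_sample; ++i) {
    int j = i + (int)(unif_rand() * (double)(N - i)) % (N - i);
    std::swap(idx[i], idx[j]);
  }

  // keep columns segregating within the sample, sorted by position
  std::vector<int> counts(p.S, 0);
  for (int i = 0; i < n_sample; ++i) {
    const unsigned char *r = p.row(idx[i]);
    for (int c = 0; c < p.S; ++c) counts[c] += r[c];
  }
  std::vector<int> keep;
  for (int c = 0; c < p.S; ++c)
    if (counts[c] > 0 && counts[c] < n_sample) keep.push_back(c);
  std::vector<size_t> ord(keep.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t a, size_t b) {
    return p.pos[keep[a]] < p.pos[keep[b]];
  });

  IntegerMatrix geno((int)keep.size(), n_sample);
  IntegerVector out_pos((int)keep.size());
  for (size_t r = 0; r < ord.size(); ++r) {
    int c = keep[ord[r]];
    out_pos[(int)r] = p.pos[c];
    for (int i = 0; i < n_sample; ++i)
      geno((int)r, i) = p.row(idx[i])[c];
  }

  return List::create(_["pos"] = out_pos, _["geno"] = geno,
                      _["trajectory"] = NumericVector(traj.begin(), traj.end()),
                      _["fixation_gen"] = fixation_gen,
                      _["n_restarts"] = n_restarts);
}
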