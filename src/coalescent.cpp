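// Structured-coalescent engine: demes, backward-time event programs
// (splits, admixture pulses, migration/size changes), branch-length and
// infinite-sites mutation output for joint SFS computation.
//
// Conventions: diploid Ne (pairwise coalescence rate 1/(2Ne) per generation);
// migration matrix entries m[d][e] are backward per-generation probabilities
// that a lineage currently in d traces back to e; times in generations.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

namespace {

// SplitMix64: counter-based stream derivation so per-simulation streams are
// independent of how many simulations ran before (parallel-safe seeding).
inline uint64_t splitmix64(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  return x ^ (x >> 31);
}

// xoshiro256** — small, fast, reproducible across platforms (no reliance on
// std::distribution implementation details).
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    for (int i = 0; i < 4; ++i) { seed = splitmix64(seed); s[i] = seed; }
  }
  static inline uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[1] * 5, 7) * 9;
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3]; s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); } // [0,1)
  double unif_pos() { double u; do { u = unif(); } while (u <= 0.0); return u; }
  double rexp(double rate) { return -std::log(unif_pos()) / rate; }
  int poisson(double lambda) {
    if (lambda <= 0.0) return 0;
    if (lambda < 30.0) {             // Knuth
      double L = std::exp(-lambda), p = 1.0; int k = 0;
      do { ++k; p *= unif_pos(); } while (p > L);
      return k - 1;
    }
    // normal approximation with continuity correction (large lambda)
    double u1 = unif_pos(), u2 = unif();
    double z = std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
    double x = lambda + std::sqrt(lambda) * z;
    return x < 0 ? 0 : (int)(x + 0.5);
  }
  int unif_int(int n) { return (int)(unif() * n) % n; } // 0..n-1
};

struct Event {
  double time;
  int kind;      // 0 split, 1 pulse, 2 migration_change, 3 size_change
  int src, dst;  // 0-based deme indices (dst unused for kinds 2,3)
  double value;  // fraction (pulse), new Ne (size_change)
  int mat;       // index into matrix list (migration_change), else -1
};

struct Demog {
  int n_demes;
  std::vector<double> Ne0;
  std::vector<int> samples;                 // haploids per deme
  std::vector<double> mig0;                 // n x n row-major
  std::vector<Event> events;
  std::vector<std::vector<double>> mats;
  std::vector<int> samp_idx;                // deme -> sampled-axis index or -1
  std::vector<int> samp_n;                  // haploids per sampled axis
  int n_samp;                               // number of sampled axes
  int n_tot;                                // total haploid samples
};

Demog parse_demog(const List& demog) {
  Demog D;
  NumericVector Ne = demog["Ne"];
  IntegerVector samples = demog["samples"];
  NumericMatrix mig = demog["migration"];
  D.n_demes = Ne.size();
  D.Ne0.assign(Ne.begin(), Ne.end());
  D.samples.assign(samples.begin(), samples.end());
  D.mig0.assign(D.n_demes * D.n_demes, 0.0);
  for (int i = 0; i < D.n_demes; ++i)
    for (int j = 0; j < D.n_demes; ++j)
      D.mig0[i * D.n_demes + j] = mig(i, j);
  DataFrame ev = as<DataFrame>(demog["events"]);
  NumericVector etime = ev["time"]; IntegerVector ekind = ev["kind"];
  IntegerVector esrc = ev["src"]; IntegerVector edst = ev["dst"];
  NumericVector evalue = ev["value"]; IntegerVector emat = ev["mat"];
  for (int i = 0; i < etime.size(); ++i) {
    Event e{etime[i], ekind[i], esrc[i], edst[i], evalue[i], emat[i]};
    D.events.push_back(e);
  }
  List mats = demog["mats"];
  for (int i = 0; i < mats.size(); ++i) {
    NumericMatrix m = mats[i];
    std::vector<double> v(D.n_demes * D.n_demes);
    for (int a = 0; a < D.n_demes; ++a)
      for (int b = 0; b < D.n_demes; ++b) v[a * D.n_demes + b] = m(a, b);
    D.mats.push_back(v);
  }
  D.samp_idx.assign(D.n_demes, -1);
  D.n_samp = 0; D.n_tot = 0;
  for (int d = 0; d < D.n_demes; ++d) {
    if (D.samples[d] > 0) {
      D.samp_idx[d] = D.n_samp++;
      D.samp_n.push_back(D.samples[d]);
      D.n_tot += D.samples[d];
    }
  }
  return D;
}

// One recorded branch of a genealogy: length + descendant counts per sampled axis.
struct BranchRec { double len; std::vector<uint16_t> desc; };

const long long STEP_GUARD = 1000000000LL;

// Simulate one genealogy; append (len, desc) for every non-root lineage.
void sim_genealogy(const Demog& D, Rng& rng, std::vector<BranchRec>& out) {
  int nd = D.n_demes;
  std::vector<double> Ne = D.Ne0;
  std::vector<double> mig = D.mig0;
  std::vector<char> active(nd, 1);

  struct Lin { double birth; std::vector<uint16_t> desc; };
  std::vector<Lin> lin;
  std::vector<std::vector<int>> members(nd);
  for (int d = 0; d < nd; ++d) {
    for (int s = 0; s < D.samples[d]; ++s) {
      Lin L; L.birth = 0.0; L.desc.assign(D.n_samp, 0);
      L.desc[D.samp_idx[d]] = 1;
      members[d].push_back((int)lin.size());
      lin.push_back(std::move(L));
    }
  }
  int nlive = D.n_tot;
  double t = 0.0;
  size_t evi = 0;
  long long steps = 0;

  std::vector<double> coal(nd), migout(nd);

  auto end_lineage = [&](int id, double when) {
    out.push_back(BranchRec{when - lin[id].birth, lin[id].desc});
  };

  while (nlive > 1) {
    if (++steps > STEP_GUARD)
      stop("coalescent event guard exceeded (pathological demography?)");
    double R = 0.0;
    for (int d = 0; d < nd; ++d) {
      coal[d] = 0.0; migout[d] = 0.0;
      if (!active[d] || members[d].empty()) continue;
      double kd = (double)members[d].size();
      if (kd >= 2) { coal[d] = kd * (kd - 1.0) / 2.0 / (2.0 * Ne[d]); R += coal[d]; }
      double mr = 0.0;
      for (int e = 0; e < nd; ++e)
        if (e != d && active[e]) mr += mig[d * nd + e];
      migout[d] = kd * mr; R += migout[d];
    }
    double t_ev = (evi < D.events.size()) ? D.events[evi].time : R_PosInf;
    double dt = (R > 0.0) ? rng.rexp(R) : R_PosInf;
    if (R <= 0.0 && !std::isfinite(t_ev))
      stop("demography never coalesces to a single ancestor (disconnected demes with no remaining events)");
    if (t + dt >= t_ev) {
      t = t_ev;
      const Event& e = D.events[evi++];
      switch (e.kind) {
        case 0: { // split: all src lineages -> dst; src deactivated
          for (int id : members[e.src]) members[e.dst].push_back(id);
          members[e.src].clear();
          active[e.src] = 0;
          break;
        }
        case 1: { // admixture pulse: fraction of src lineages -> dst
          if (e.value >= 1.0) {
            for (int id : members[e.src]) members[e.dst].push_back(id);
            members[e.src].clear();
          } else if (e.value > 0.0) {
            std::vector<int> keep;
            for (int id : members[e.src]) {
              if (rng.unif() < e.value) members[e.dst].push_back(id);
              else keep.push_back(id);
            }
            members[e.src].swap(keep);
          }
          break;
        }
        case 2: mig = D.mats[e.mat]; break;
        case 3: Ne[e.src] = e.value; break;
      }
      continue;
    }
    t += dt;
    double u = rng.unif() * R;
    int dpick = -1; bool is_coal = false;
    for (int d = 0; d < nd; ++d) {
      if (u < coal[d]) { dpick = d; is_coal = true; break; }
      u -= coal[d];
      if (u < migout[d]) { dpick = d; is_coal = false; break; }
      u -= migout[d];
    }
    if (dpick < 0) { dpick = nd - 1; is_coal = coal[nd - 1] > 0; } // fp guard
    if (is_coal) {
      std::vector<int>& mem = members[dpick];
      int k = (int)mem.size();
      int i = rng.unif_int(k);
      int j = rng.unif_int(k - 1); if (j >= i) ++j;
      int a = mem[i], b = mem[j];
      end_lineage(a, t); end_lineage(b, t);
      Lin L; L.birth = t; L.desc = lin[a].desc;
      for (int s = 0; s < D.n_samp; ++s) L.desc[s] += lin[b].desc[s];
      int hi = std::max(i, j), lo = std::min(i, j);
      mem[hi] = mem.back(); mem.pop_back();
      mem[lo] = mem.back(); mem.pop_back();
      members[dpick].push_back((int)lin.size());
      lin.push_back(std::move(L));
      --nlive;
    } else {
      std::vector<int>& mem = members[dpick];
      int i = rng.unif_int((int)mem.size());
      double mr = 0.0;
      for (int e = 0; e < nd; ++e)
        if (e != dpick && active[e]) mr += mig[dpick * nd + e];
      double v = rng.unif() * mr;
      int epick = -1;
      for (int e = 0; e < nd; ++e) {
        if (e == dpick || !active[e]) continue;
        if (v < mig[dpick * nd + e]) { epick = e; break; }
        v -= mig[dpick * nd + e];
      }
      if (epick < 0) continue;
      int id = mem[i];
      mem[i] = mem.back(); mem.pop_back();
      members[epick].push_back(id);
    }
  }
}

inline size_t cell_index(const BranchRec& b, const std::vector<size_t>& stride) {
  size_t idx = 0;
  for (size_t s = 0; s < stride.size(); ++s) idx += (size_t)b.desc[s] * stride[s];
  return idx;
}

std::vector<size_t> make_strides(const Demog& D) {
  std::vector<size_t> stride(D.n_samp);
  size_t acc = 1;
  for (int s = 0; s < D.n_samp; ++s) { stride[s] = acc; acc *= (size_t)(D.samp_n[s] + 1); }
  return stride;
}

} // namespace

// Branch-length joint SFS: expected per-cell branch length, summed over
// n_sims genealogies (column-major over dims samp_n+1).
// [[Rcpp::export]]
List cpp_branch_sfs(List demog, int n_sims, double seed) {
  Demog D = parse_demog(demog);
  std::vector<size_t> stride = make_strides(D);
  size_t ncell = 1;
  for (int s = 0; s < D.n_samp; ++s) ncell *= (size_t)(D.samp_n[s] + 1);
  if (ncell > 50000000) stop("joint SFS too large; reduce sample sizes or project");
  std::vector<double> cells(ncell, 0.0);
  std::vector<BranchRec> branches;
  double tot_len = 0.0;
  uint64_t root = (uint64_t)seed;
  for (int i = 0; i < n_sims; ++i) {
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
    Rng rng(splitmix64(root ^ (0x51F5ULL * (uint64_t)(i + 1))));
    branches.clear();
    sim_genealogy(D, rng, branches);
    for (const BranchRec& b : branches) {
      cells[cell_index(b, stride)] += b.len;
      tot_len += b.len;
    }
  }
  IntegerVector dims(D.n_samp);
  for (int s = 0; s < D.n_samp; ++s) dims[s] = D.samp_n[s] + 1;
  return List::create(_["cells"] = NumericVector(cells.begin(), cells.end()),
                      _["dims"] = dims,
                      _["mean_total_length"] = tot_len / n_sims,
                      _["n_sims"] = n_sims);
}

// Infinite-sites mutation-mode joint SFS over independent single-site loci:
// Poisson(mu * total branch length) mutations per locus, each placed on a
// branch with probability proportional to its length.
// [[Rcpp::export]]
List cpp_mutation_sfs(List demog, int n_loci, double mu, double seed) {
  Demog D = parse_demog(demog);
  std::vector<size_t> stride = make_strides(D);
  size_t ncell = 1;
  for (int s = 0; s < D.n_samp; ++s) ncell *= (size_t)(D.samp_n[s] + 1);
  if (ncell > 50000000) stop("joint SFS too large; reduce sample sizes or project");
  std::vector<double> cells(ncell, 0.0);
  int n_mono = 0; long long n_mut = 0;
  std::vector<BranchRec> branches;
  uint64_t root = (uint64_t)seed;
  for (int i = 0; i < n_loci; ++i) {
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
    Rng rng(splitmix64(root ^ (0xA11CULL * (uint64_t)(i + 1))));
    branches.clear();
    sim_genealogy(D, rng, branches);
    double L = 0.0;
    for (const BranchRec& b : branches) L += b.len;
    int k = rng.poisson(mu * L);
    if (k == 0) { ++n_mono; continue; }
    for (int m = 0; m < k; ++m) {
      double u = rng.unif() * L, acc = 0.0;
      size_t pick = branches.size() - 1;
      for (size_t bi = 0; bi < branches.size(); ++bi) {
        acc += branches[bi].len;
        if (u < acc) { pick = bi; break; }
      }
      cells[cell_index(branches[pick], stride)] += 1.0;
      ++n_mut;
    }
  }
  IntegerVector dims(D.n_samp);
  for (int s = 0; s < D.n_samp; ++s) dims[s] = D.samp_n[s] + 1;
  return List::create(_["cells"] = NumericVector(cells.begin(), cells.end()),
                      _["dims"] = dims,
                      _["n_mutations"] = (double)n_mut,
                      _["n_monomorphic_loci"] = n_mono);
}

// Segregating sites conditional on polymorphism: n_genealogies genealogies,
// sites assigned to genealogies proportional to total branch length and to
// branches proportional to length (the infinite-sites distribution of a
// segregating site). Returns n_sites x n_sampled_demes derived-allele counts.
// [[Rcpp::export]]
IntegerMatrix cpp_conditional_sites(List demog, int n_sites, int n_genealogies,
                                    double seed) {
  Demog D = parse_demog(demog);
  std::vector<double> lens;          // all branch lengths, flat
  std::vector<uint16_t> descs;       // n_samp per branch, flat
  std::vector<size_t> g_off;         // genealogy -> first branch index
  std::vector<double> g_len;         // genealogy total length (cumulative later)
  std::vector<BranchRec> branches;
  uint64_t root = (uint64_t)seed;
  for (int i = 0; i < n_genealogies; ++i) {
    if (i % 1024 == 0) Rcpp::checkUserInterrupt();
    Rng rng(splitmix64(root ^ (0xC095ULL * (uint64_t)(i + 1))));
    branches.clear();
    sim_genealogy(D, rng, branches);
    g_off.push_back(lens.size());
    double L = 0.0;
    for (const BranchRec& b : branches) {
      lens.push_back(b.len);
      for (int s = 0; s < D.n_samp; ++s) descs.push_back(b.desc[s]);
      L += b.len;
    }
    g_len.push_back(L);
  }
  g_off.push_back(lens.size());
  std::vector<double> cum(g_len.size());
  double tot = 0.0;
  for (size_t j = 0; j < g_len.size(); ++j) { tot += g_len[j]; cum[j] = tot; }
  if (tot <= 0.0) stop("all genealogies have zero branch length (mu irrelevant here; check demography)");
  IntegerMatrix out(n_sites, D.n_samp);
  Rng rng(splitmix64(root ^ 0x517E5ULL));
  for (int s = 0; s < n_sites; ++s) {
    double u = rng.unif() * tot;
    size_t j = std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
    if (j >= g_len.size()) j = g_len.size() - 1;
    double v = rng.unif() * g_len[j], acc = 0.0;
    size_t pick = g_off[j + 1] - 1;
    for (size_t bi = g_off[j]; bi < g_off[j + 1]; ++bi) {
      acc += lens[bi];
      if (v < acc) { pick = bi; break; }
    }
    for (int a = 0; a < D.n_samp; ++a) out(s, a) = descs[pick * D.n_samp + a];
  }
  return out;
}
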