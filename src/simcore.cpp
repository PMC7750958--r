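// Individual-based forward simulator of a DNA-transposon invasion with
// internal deletions (IDs), piRNA-cluster trapping and 1D stepping-stone
// migration.
//
// State crossing the R boundary:
//   population matrix: columns individual (1-based), haplotype (1|2),
//     chrom (1-based), pos (1-based bp), variant (0 = full-length, >0 = ID id)
//   variant matrix: one row per ID variant id (row i = id i), columns
//     id, start, end (1-based inclusive breakpoints on the TE consensus)
//
// All randomness is drawn from R's RNG stream, so set.seed() in R makes
// every entry point reproducible.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <unordered_set>
#include <map>
#include <string>
#include <cmath>

using namespace Rcpp;

namespace {

struct Ins {
  int chrom;  // 0-based internally
  int pos;    // 1-based bp
  int var;    // 0 = FL
};

inline bool ins_lt(const Ins& a, const Ins& b) {
  if (a.chrom != b.chrom) return a.chrom < b.chrom;
  if (a.pos != b.pos) return a.pos < b.pos;
  return a.var < b.var;
}

typedef std::vector<Ins> Hap;

struct Indiv {
  Hap h[2];
  int copies() const { return (int)(h[0].size() + h[1].size()); }
};

typedef std::vector<Indiv> Pop;

struct Cfg {
  std::vector<int> clen;     // chromosome lengths (bp)
  std::vector<int> cluster;  // piRNA cluster lengths (bp), terminal window
  std::vector<double> rr;    // recombination rate (cM/Mb)
  double u;                  // transposition rate per copy per generation
  double c;                  // conversion rate (FL -> fresh ID per event)
  double x;                  // per-copy fitness cost
  double fl_id;              // per-copy mobilization weight of FL copies
  int N;                     // diploid population size
  int L;                     // TE consensus length (bp)
  double genome_total;       // sum of chromosome lengths
};

Cfg parse_cfg(const List& cfg) {
  Cfg out;
  IntegerVector clen = cfg["chrom_len"];
  IntegerVector cluster = cfg["cluster_len"];
  NumericVector rr = cfg["rr"];
  out.clen.assign(clen.begin(), clen.end());
  out.cluster.assign(cluster.begin(), cluster.end());
  out.rr.assign(rr.begin(), rr.end());
  out.u = as<double>(cfg["u"]);
  out.c = as<double>(cfg["c"]);
  out.x = as<double>(cfg["x"]);
  out.fl_id = as<double>(cfg["fl_id"]);
  out.N = as<int>(cfg["N"]);
  out.L = as<int>(cfg["consensus_len"]);
  out.genome_total = 0.0;
  for (size_t i = 0; i < out.clen.size(); ++i) out.genome_total += out.clen[i];
  return out;
}

// ID variant registry: breakpoints of variant id i live at index i-1
struct VarReg {
  std::vector<int> start, end;
  int add(int s, int e) {
    start.push_back(s);
    end.push_back(e);
    return (int)start.size();
  }
};

VarReg parse_variants(const IntegerMatrix& vm) {
  VarReg reg;
  for (int i = 0; i < vm.nrow(); ++i) {
    reg.start.push_back(vm(i, 1));
    reg.end.push_back(vm(i, 2));
  }
  return reg;
}

IntegerMatrix variants_to_matrix(const VarReg& reg) {
  int n = (int)reg.start.size();
  IntegerMatrix vm(n, 3);
  for (int i = 0; i < n; ++i) {
    vm(i, 0) = i + 1;
    vm(i, 1) = reg.start[i];
    vm(i, 2) = reg.end[i];
  }
  colnames(vm) = CharacterVector::create("id", "start", "end");
  return vm;
}

Pop pop_from_matrix(const IntegerMatrix& pm, int N) {
  Pop pop(N);
  for (int i = 0; i < pm.nrow(); ++i) {
    int ind = pm(i, 0) - 1, hap = pm(i, 1) - 1;
    if (ind < 0 || ind >= N) stop("individual index out of range");
    if (hap < 0 || hap > 1) stop("haplotype must be 1 or 2");
    Ins x;
    x.chrom = pm(i, 2) - 1;
    x.pos = pm(i, 3);
    x.var = pm(i, 4);
    pop[ind].h[hap].push_back(x);
  }
  for (int i = 0; i < N; ++i)
    for (int h = 0; h < 2; ++h)
      std::sort(pop[i].h[h].begin(), pop[i].h[h].end(), ins_lt);
  return pop;
}

IntegerMatrix pop_to_matrix(const Pop& pop) {
  int total = 0;
  for (size_t i = 0; i < pop.size(); ++i) total += pop[i].copies();
  IntegerMatrix pm(total, 5);
  int r = 0;
  for (size_t i = 0; i < pop.size(); ++i)
    for (int h = 0; h < 2; ++h)
      for (size_t k = 0; k < pop[i].h[h].size(); ++k) {
        const Ins& x = pop[i].h[h][k];
        pm(r, 0) = (int)i + 1;
        pm(r, 1) = h + 1;
        pm(r, 2) = x.chrom + 1;
        pm(r, 3) = x.pos;
        pm(r, 4) = x.var;
        ++r;
      }
  colnames(pm) =
      CharacterVector::create("individual", "haplotype", "chrom", "pos", "variant");
  return pm;
}

inline bool in_cluster(const Ins& x, const Cfg& cfg) {
  return x.pos > cfg.clen[x.chrom] - cfg.cluster[x.chrom];
}

bool is_active(const Indiv& ind, const Cfg& cfg) {
  bool has_fl = false;
  for (int h = 0; h < 2; ++h)
    for (size_t k = 0; k < ind.h[h].size(); ++k) {
      const Ins& x = ind.h[h][k];
      if (in_cluster(x, cfg)) return false;
      if (x.var == 0) has_fl = true;
    }
  return has_fl;
}

inline int runif_int(int n) {  // uniform on 0..n-1
  int v;
  do {
    v = (int)std::floor(unif_rand() * n);
  } while (v >= n);
  return v;
}

// one haploid gamete from a diploid parent, per the recombination map
Hap make_gamete(const Indiv& parent, const Cfg& cfg) {
  Hap gam;
  int C = (int)cfg.clen.size();
  for (int ch = 0; ch < C; ++ch) {
    double lambda = cfg.rr[ch] / 100.0 * (cfg.clen[ch] / 1e6);
    int k = (lambda > 0) ? (int)R::rpois(lambda) : 0;
    int start_hap = (unif_rand() < 0.5) ? 0 : 1;
    if (k == 0) {
      for (size_t i = 0; i < parent.h[start_hap].size(); ++i)
        if (parent.h[start_hap][i].chrom == ch) gam.push_back(parent.h[start_hap][i]);
    } else {
      std::vector<double> cx(k);
      for (int i = 0; i < k; ++i) cx[i] = unif_rand() * cfg.clen[ch];
      std::sort(cx.begin(), cx.end());
      for (int h = 0; h < 2; ++h)
        for (size_t i = 0; i < parent.h[h].size(); ++i) {
          const Ins& x = parent.h[h][i];
          if (x.chrom != ch) continue;
          // crossovers strictly before the insertion position flip the source
          int nflip = (int)(std::lower_bound(cx.begin(), cx.end(), (double)x.pos) -
                            cx.begin());
          if ((start_hap + nflip) % 2 == h) gam.push_back(x);
        }
    }
  }
  std::sort(gam.begin(), gam.end(), ins_lt);
  return gam;
}

int fresh_id_variant(const Cfg& cfg, VarReg& reg) {
  int a, b;
  do {
    a = 1 + runif_int(cfg.L);
    b = 1 + runif_int(cfg.L);
  } while (a == b);
  return reg.add(std::min(a, b), std::max(a, b));
}

// Transposition events in the nascent germline (the gamete); the caller has
// already checked that the diploid parent is active. Cut-and-paste with gap
// repair: each event copies a template element of the gamete to a new site.
// The pasted copy is a complete copy of the template (FL stays FL, an ID
// keeps its breakpoints). When the template is FL, the interrupted gap
// repair at the donor site converts the transposing element itself into a
// fresh ID with probability c; ID elements cannot accumulate further
// deletions. Event count ~ Poisson(u * gamete copy number); per-copy
// mobilization weight is fl_id for FL and 1 - fl_id for ID copies.
void transpose_into_gamete(Hap& gam, const Cfg& cfg, VarReg& reg) {
  int n0 = (int)gam.size();
  if (n0 == 0 || cfg.u <= 0) return;
  int m = (int)R::rpois(cfg.u * n0);
  if (m == 0) return;

  std::unordered_set<long long> occupied;
  for (size_t i = 0; i < gam.size(); ++i)
    occupied.insert((long long)gam[i].chrom * 2000000000LL + gam[i].pos);

  for (int e = 0; e < m; ++e) {
    // template drawn over the gamete's current copies (new copies included)
    int n_fl = 0, n_id = 0;
    for (size_t i = 0; i < gam.size(); ++i)
      (gam[i].var == 0 ? n_fl : n_id) += 1;
    double w_fl = cfg.fl_id * n_fl, w_id = (1.0 - cfg.fl_id) * n_id;
    if (w_fl + w_id <= 0) break;  // no template carries mobilization weight
    double r = unif_rand() * (w_fl + w_id);
    bool pick_fl = r < w_fl;
    int tmpl = -1, seen = 0, target = runif_int(pick_fl ? n_fl : n_id);
    for (size_t i = 0; i < gam.size(); ++i) {
      bool is_fl = gam[i].var == 0;
      if (is_fl == pick_fl && seen++ == target) {
        tmpl = (int)i;
        break;
      }
    }
    // paste a complete copy of the template at a uniform unoccupied site,
    // chromosome weighted by length
    Ins x;
    x.var = gam[tmpl].var;
    for (;;) {
      double rs = unif_rand() * cfg.genome_total;
      int ch = 0;
      while (ch + 1 < (int)cfg.clen.size() && rs >= cfg.clen[ch]) {
        rs -= cfg.clen[ch];
        ++ch;
      }
      x.chrom = ch;
      x.pos = 1 + (int)std::floor(rs);
      if (x.pos > cfg.clen[ch]) x.pos = cfg.clen[ch];
      long long key = (long long)ch * 2000000000LL + x.pos;
      if (occupied.insert(key).second) break;
    }
    gam.push_back(x);
    // interrupted gap repair converts the transposing FL element in place
    if (pick_fl && cfg.c > 0 && unif_rand() < cfg.c) {
      gam[tmpl].var = fresh_id_variant(cfg, reg);
    }
  }
  std::sort(gam.begin(), gam.end(), ins_lt);
}

int sample_weighted(const std::vector<double>& cw) {
  double r = unif_rand() * cw.back();
  return (int)(std::upper_bound(cw.begin(), cw.end(), r) - cw.begin());
}

Pop step_generation(const Pop& pop, const Cfg& cfg, VarReg& reg) {
  int N = (int)pop.size();
  std::vector<double> cw(N);
  std::vector<bool> active(N);
  double acc = 0.0;
  for (int i = 0; i < N; ++i) {
    double w = std::max(0.0, 1.0 - cfg.x * pop[i].copies());
    acc += w;
    cw[i] = acc;
    active[i] = is_active(pop[i], cfg);
  }
  if (acc <= 0) stop("population extinct: all fitness values are zero");
  Pop next(cfg.N);
  for (int o = 0; o < cfg.N; ++o) {
    int p1 = sample_weighted(cw);
    int p2 = p1;
    if (N > 1) {
      do {
        p2 = sample_weighted(cw);
      } while (p2 == p1);
    }
    Hap g1 = make_gamete(pop[p1], cfg);
    if (active[p1]) transpose_into_gamete(g1, cfg, reg);
    Hap g2 = make_gamete(pop[p2], cfg);
    if (active[p2]) transpose_into_gamete(g2, cfg, reg);
    next[o].h[0] = g1;
    next[o].h[1] = g2;
  }
  return next;
}

void migrate(const Pop& source, Pop& target, int m) {
  int N = (int)source.size();
  if (m > N) stop("migrant count exceeds population size");
  if (m == 0) return;
  // m distinct source individuals copied over m distinct target slots
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  for (int i = 0; i < m; ++i) std::swap(idx[i], idx[i + runif_int(N - i)]);
  std::vector<int> tgt(target.size());
  for (size_t i = 0; i < target.size(); ++i) tgt[i] = (int)i;
  for (int i = 0; i < m; ++i)
    std::swap(tgt[i], tgt[i + runif_int((int)target.size() - i)]);
  for (int i = 0; i < m; ++i) target[tgt[i]] = source[idx[i]];
}

struct PopStats {
  double copies_total, id_copies, cluster_ins;
  int n_variants;
};

PopStats pop_stats(const Pop& pop, const Cfg& cfg) {
  PopStats s;
  s.copies_total = s.id_copies = s.cluster_ins = 0;
  std::unordered_set<int> vars;
  for (size_t i = 0; i < pop.size(); ++i)
    for (int h = 0; h < 2; ++h)
      for (size_t k = 0; k < pop[i].h[h].size(); ++k) {
        const Ins& x = pop[i].h[h][k];
        s.copies_total += 1;
        if (x.var > 0) {
          s.id_copies += 1;
          vars.insert(x.var);
        }
        if (in_cluster(x, cfg)) s.cluster_ins += 1;
      }
  s.n_variants = (int)vars.size();
  return s;
}

// variant id -> copy count, plus total copies
DataFrame fingerprint_counts(const Pop& pop, const VarReg& reg) {
  std::map<int, int> cnt;
  long total = 0;
  for (size_t i = 0; i < pop.size(); ++i)
    for (int h = 0; h < 2; ++h)
      for (size_t k = 0; k < pop[i].h[h].size(); ++k) {
        ++total;
        int v = pop[i].h[h][k].var;
        if (v > 0) ++cnt[v];
      }
  int n = (int)cnt.size();
  IntegerVector var(n), start(n), end(n), count(n);
  int j = 0;
  for (std::map<int, int>::iterator it = cnt.begin(); it != cnt.end(); ++it, ++j) {
    var[j] = it->first;
    start[j] = reg.start[it->first - 1];
    end[j] = reg.end[it->first - 1];
    count[j] = it->second;
  }
  return DataFrame::create(_["variant"] = var, _["start"] = start, _["end"] = end,
                           _["count"] = count,
                           _["total_copies"] = IntegerVector(n, (int)total));
}

}  // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_init_population(int N, IntegerVector chrom_len, int n_fl) {
  double total_sites = 0;
  for (int i = 0; i < chrom_len.size(); ++i) total_sites += chrom_len[i];
  if (n_fl > total_sites) stop("more initial insertions than genomic sites");
  std::unordered_set<long long> used;
  IntegerMatrix pm(n_fl, 5);
  for (int i = 0; i < n_fl; ++i) {
    int ch, pos;
    for (;;) {
      double r = unif_rand() * total_sites;
      ch = 0;
      while (ch + 1 < chrom_len.size() && r >= chrom_len[ch]) {
        r -= chrom_len[ch];
        ++ch;
      }
      pos = 1 + (int)std::floor(r);
      if (pos > chrom_len[ch]) pos = chrom_len[ch];
      if (used.insert((long long)ch * 2000000000LL + pos).second) break;
    }
    pm(i, 0) = 1 + runif_int(N);
    pm(i, 1) = 1 + (unif_rand() < 0.5 ? 0 : 1);
    pm(i, 2) = ch + 1;
    pm(i, 3) = pos;
    pm(i, 4) = 0;
  }
  colnames(pm) =
      CharacterVector::create("individual", "haplotype", "chrom", "pos", "variant");
  return pm;
}

// [[Rcpp::export]]
bool cpp_is_active(IntegerMatrix ind_ins, List cfg) {
  Cfg C = parse_cfg(cfg);
  Indiv ind;
  for (int i = 0; i < ind_ins.nrow(); ++i) {
    Ins x;
    x.chrom = ind_ins(i, 2) - 1;
    x.pos = ind_ins(i, 3);
    x.var = ind_ins(i, 4);
    int h = ind_ins(i, 1) - 1;
    ind.h[h].push_back(x);
  }
  return is_active(ind, C);
}

// [[Rcpp::export]]
IntegerMatrix cpp_make_gamete(IntegerMatrix parent_ins, List cfg) {
  Cfg C = parse_cfg(cfg);
  Pop p = pop_from_matrix(parent_ins, 1);
  Hap g = make_gamete(p[0], C);
  IntegerMatrix gm((int)g.size(), 3);
  for (size_t i = 0; i < g.size(); ++i) {
    gm(i, 0) = g[i].chrom + 1;
    gm(i, 1) = g[i].pos;
    gm(i, 2) = g[i].var;
  }
  colnames(gm) = CharacterVector::create("chrom", "pos", "variant");
  return gm;
}

// [[Rcpp::export]]
List cpp_transpose_into_gamete(IntegerMatrix parent_ins, IntegerMatrix gamete,
                               IntegerMatrix variants, List cfg) {
  Cfg C = parse_cfg(cfg);
  Pop p = pop_from_matrix(parent_ins, 1);
  VarReg reg = parse_variants(variants);
  Hap g;
  for (int i = 0; i < gamete.nrow(); ++i) {
    Ins x;
    x.chrom = gamete(i, 0) - 1;
    x.pos = gamete(i, 1);
    x.var = gamete(i, 2);
    g.push_back(x);
  }
  if (is_active(p[0], C)) transpose_into_gamete(g, C, reg);
  IntegerMatrix gm((int)g.size(), 3);
  for (size_t i = 0; i < g.size(); ++i) {
    gm(i, 0) = g[i].chrom + 1;
    gm(i, 1) = g[i].pos;
    gm(i, 2) = g[i].var;
  }
  colnames(gm) = CharacterVector::create("chrom", "pos", "variant");
  return List::create(_["gamete"] = gm, _["variants"] = variants_to_matrix(reg));
}

// [[Rcpp::export]]
List cpp_step_generation(IntegerMatrix pop_ins, IntegerMatrix variants, List cfg) {
  Cfg C = parse_cfg(cfg);
  Pop pop = pop_from_matrix(pop_ins, C.N);
  VarReg reg = parse_variants(variants);
  Pop next = step_generation(pop, C, reg);
  PopStats s = pop_stats(next, C);
  return List::create(
      _["population"] = pop_to_matrix(next),
      _["variants"] = variants_to_matrix(reg),
      _["stats"] = NumericVector::create(
          _["copy_number"] = s.copies_total / C.N,
          _["fraction_id"] =
              s.copies_total > 0 ? s.id_copies / s.copies_total : NA_REAL,
          _["cluster_insertions"] = s.cluster_ins,
          _["n_variants"] = (double)s.n_variants));
}

// [[Rcpp::export]]
List cpp_migrate(IntegerMatrix source_ins, IntegerMatrix target_ins, int m, int N) {
  Pop src = pop_from_matrix(source_ins, N);
  Pop tgt = pop_from_matrix(target_ins, N);
  migrate(src, tgt, m);
  return List::create(_["source"] = pop_to_matrix(src),
                      _["target"] = pop_to_matrix(tgt));
}

// Full run: single population (n_pops = 1) or 1D stepping stone.
// Migration happens after the reproduction step of generation t whenever
// t is a multiple of mig_interval and a naive population remains; m migrants
// are copied from the most recently seeded population into the next one.
// [[Rcpp::export]]
List cpp_run_invasion(List cfg, int n_pops, int n_fl, int generations,
                      int record_every, int mig_interval, int mig_m,
                      IntegerVector sample_gens) {
  Cfg C = parse_cfg(cfg);
  VarReg reg;
  std::vector<Pop> pops(n_pops);
  for (int p = 0; p < n_pops; ++p) pops[p] = Pop(C.N);
  {
    IntegerVector clen(C.clen.begin(), C.clen.end());
    IntegerMatrix init = cpp_init_population(C.N, clen, n_fl);
    pops[0] = pop_from_matrix(init, C.N);
  }
  std::unordered_set<int> sample_set(sample_gens.begin(), sample_gens.end());
  int last_seeded = 0;

  std::vector<int> rec_gen, rec_pop, rec_nvar;
  std::vector<double> rec_cn, rec_fid, rec_clu;
  List fp_out;
  std::vector<std::string> fp_names;

  for (int t = 0; t <= generations; ++t) {
    if (t > 0) {
      for (int p = 0; p <= last_seeded; ++p) {
        // naive and already-empty populations have nothing to transmit,
        // but seeded populations are always stepped (drift applies)
        pops[p] = step_generation(pops[p], C, reg);
      }
      if (mig_interval > 0 && mig_m > 0 && t % mig_interval == 0 &&
          last_seeded + 1 < n_pops) {
        migrate(pops[last_seeded], pops[last_seeded + 1], mig_m);
        ++last_seeded;
      }
    }
    bool record = (record_every > 0 && t % record_every == 0) || t == generations;
    if (record) {
      for (int p = 0; p < n_pops; ++p) {
        PopStats s = pop_stats(pops[p], C);
        rec_gen.push_back(t);
        rec_pop.push_back(p + 1);
        rec_cn.push_back(s.copies_total / C.N);
        rec_fid.push_back(s.copies_total > 0 ? s.id_copies / s.copies_total
                                             : NA_REAL);
        rec_clu.push_back(s.cluster_ins);
        rec_nvar.push_back(s.n_variants);
      }
    }
    if (sample_set.count(t)) {
      List fps(n_pops);
      for (int p = 0; p < n_pops; ++p) fps[p] = fingerprint_counts(pops[p], reg);
      fp_out.push_back(fps);
      fp_names.push_back(std::to_string(t));
    }
    if (t % 50 == 0) Rcpp::checkUserInterrupt();
  }
  fp_out.attr("names") = wrap(fp_names);

  DataFrame records = DataFrame::create(
      _["generation"] = wrap(rec_gen), _["population"] = wrap(rec_pop),
      _["copy_number"] = wrap(rec_cn), _["fraction_id"] = wrap(rec_fid),
      _["cluster_insertions"] = wrap(rec_clu), _["n_variants"] = wrap(rec_nvar));

  List final_pops(n_pops);
  for (int p = 0; p < n_pops; ++p) final_pops[p] = pop_to_matrix(pops[p]);

  return List::create(_["records"] = records, _["fingerprints"] = fp_out,
                      _["variants"] = variants_to_matrix(reg),
                      _["populations"] = final_pops);
}
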