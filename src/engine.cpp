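// Delayed-SSA engine for coupled nucleotide-level transcription and
// codon-level translation on a single gene.
//
// Direct-method SSA over a dynamic set of propensity slots (one slot per
// entity: promoter, protein pools, each RNAp, each RNA compartment, each
// ribosome).  Slots are created and destroyed at run time as RNA
// compartments appear and disappear.  The only delayed reaction is the
// promoter open-complex formation: when the sampled SSA waiting time would
// cross the queued release, the release is applied first and the waiting
// time is re-sampled (standard delayed-SSA semantics).
//
// All randomness is drawn from R's RNG so that set.seed() makes a run
// bitwise reproducible.

#include <Rcpp.h>
#include <vector>
#include <deque>
#include <map>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Fenwick (binary indexed) tree over propensity slots: O(log n) update and
// O(log n) selection proportional to propensity.

struct PropTree {
  int cap = 0;                 // power of two capacity
  std::vector<double> bit;     // 1-based internal nodes
  std::vector<double> val;     // per-slot propensities (0-based)
  double tot = 0.0;

  void init(int capacity) {
    cap = 1;
    while (cap < capacity) cap <<= 1;
    bit.assign(cap + 1, 0.0);
    val.assign(cap, 0.0);
    tot = 0.0;
  }
  void grow() {
    int newcap = cap * 2;
    std::vector<double> old = val;
    init(newcap);
    for (int i = 0; i < (int)old.size(); ++i) if (old[i] != 0.0) set(i, old[i]);
  }
  void set(int slot, double v) {
    if (v < 0 && v > -1e-12) v = 0.0;  // clamp tiny negative round-off
    double delta = v - val[slot];
    if (delta == 0.0) return;
    val[slot] = v;
    for (int i = slot + 1; i <= cap; i += i & (-i)) bit[i] += delta;
    tot += delta;
  }
  void rebuild() {  // refresh sums to shed floating-point drift
    std::vector<double> old = val;
    std::fill(bit.begin(), bit.end(), 0.0);
    std::fill(val.begin(), val.end(), 0.0);
    tot = 0.0;
    for (int i = 0; i < (int)old.size(); ++i) if (old[i] != 0.0) set(i, old[i]);
  }
  // smallest slot with cumulative propensity >= r, r in (0, tot]
  int sample(double r) const {
    int pos = 0;
    int pw = cap;
    double rem = r;
    while (pw > 0) {
      int np = pos + pw;
      if (np <= cap && bit[np] < rem) { pos = np; rem -= bit[np]; }
      pw >>= 1;
    }
    int slot = pos;  // 0-based
    if (slot >= cap) slot = cap - 1;
    // guard against landing on an empty slot through round-off
    while (slot < cap && val[slot] <= 0.0) ++slot;
    if (slot >= cap) { slot = cap - 1; while (slot > 0 && val[slot] <= 0.0) --slot; }
    return slot;
  }
};

// ---------------------------------------------------------------------------

enum Phase { PH_STEPPING = 0, PH_ACTIVATED, PH_PAUSED, PH_ARRESTED, PH_EDITING };
enum CompStatus { ST_ELONG = 0, ST_COMPLETE, ST_PREM };
enum PromState { PR_FREE = 0, PR_OC_PENDING, PR_OC_DONE };
enum EntType { ENT_NONE = 0, ENT_PROMOTER, ENT_POOLS, ENT_RNAP, ENT_COMP, ENT_RIB };

// event type codes (kept in sync with event_type_labels() in R/simulate.R)
enum EvType {
  EV_TX_BIND = 1, EV_TX_OC, EV_TX_CLEAR, EV_TX_COMPLETE, EV_TX_PREMATURE,
  EV_TX_DETACH, EV_SITE_PASS, EV_SITE_TRIGGER, EV_TL_INIT, EV_TL_COMPLETE,
  EV_TL_DROP, EV_TL_TT, EV_RNA_MARK, EV_COMP_DESTROY, EV_MET_ACT
};
const int N_EV_TYPES = 15;

// event-category mask bits
const int REC_TX = 1, REC_TL = 2, REC_RNA = 4, REC_SITE = 8, REC_MET = 16;

struct Rnap {
  int uid, slot, pos, phase;
  double release_rate;   // for paused/arrested/editing phases
  int comp_uid;
  int last_site_pos;     // highest position at which a site draw was made
};

struct Rib {
  int uid, slot, pos;    // pos = active-site ribonucleotide (1-based)
  bool awaiting;         // awaiting codon activation (pos is a codon boundary)
  int steps;             // translocation sub-steps done since last activation
  int peptide;           // peptide bonds formed
  int max_codon;         // highest codon index activated (no double counting)
};

struct Comp {
  int uid, slot, front, status;
  bool marked;           // degradation-marked (RBS destroyed)
  bool counted;          // currently counted in the functional-mRNA observable
  std::deque<Rib> ribs;  // leader (highest pos) first
};

struct Params {
  double k_init, k_eff, toc_mean, toc_sd, k_m, k_a_far, k_a_near,
         k_p, tau_p, k_ar, tau_ar, k_ec, tau_c, k_pre, k_pyro, k_f, k_dr;
  double k_tr, k_tm, k_bt, k_drop, k_tt, k_trans_f, k_fold, k_dec;
  int delta_rnap, delta_rib, n_rnap, n_rib;
};

struct Engine {
  Params P;
  // gene
  int L = 0, n_codons = 0;
  std::vector<double> codon_rate;     // activation rate per codon (1..n_codons)
  std::vector<char> is_met;
  std::vector<signed char> site_kind; // per nt: -1 none, 0 long pause, 1 arrest
  std::vector<double> site_prob, site_dur;

  // state
  double t = 0.0;
  int prom_state = PR_FREE;
  double oc_time = 0.0;               // release time of pending open complex
  int free_rnap = 0, free_rib = 0;
  int mrna = 0;                       // functional-mRNA observable
  long long p_prem = 0, p = 0;
  std::deque<Rnap> rnaps;             // leader (highest pos) first
  std::map<int, Comp> comps;          // by uid (deterministic iteration)
  int next_rnap_uid = 1, next_comp_uid = 1, next_rib_uid = 1;

  PropTree tree;
  std::vector<EntType> slot_type;
  std::vector<int> slot_a, slot_b;    // entity ids (a = uid, b = comp uid for ribs)
  std::vector<int> free_slots;
  int slots_in_use = 0;
  int PROM_SLOT = -1, POOLS_SLOT = -1;

  // bookkeeping
  long long n_events = 0;
  std::vector<long long> ev_count = std::vector<long long>(N_EV_TYPES + 1, 0);
  int rec_mask = 0;
  bool check_inv = false;

  // event log
  std::vector<double> ev_time;
  std::vector<int> ev_type, ev_comp, ev_ent, ev_pos;
  std::vector<double> ev_val;

  // kymograph
  double kymo_dt = 0.0;
  std::vector<double> ky_time; std::vector<int> ky_is_rib, ky_ent, ky_comp, ky_pos;

  // sampled series
  std::vector<double> s_time;
  std::vector<int> s_mrna, s_pprem, s_p, s_free_rnap, s_free_rib,
                   s_rnaps, s_ribs, s_comps;

  int rnap_excl, rib_excl, rbs_len;

  // ---- slots ------------------------------------------------------------
  int alloc_slot(EntType ty, int a, int b) {
    int s;
    if (!free_slots.empty()) { s = free_slots.back(); free_slots.pop_back(); }
    else {
      s = (int)slot_type.size();
      if (s >= tree.cap) tree.grow();
      slot_type.push_back(ENT_NONE); slot_a.push_back(0); slot_b.push_back(0);
    }
    slot_type[s] = ty; slot_a[s] = a; slot_b[s] = b;
    ++slots_in_use;
    return s;
  }
  void free_slot(int s) {
    tree.set(s, 0.0);
    slot_type[s] = ENT_NONE; slot_a[s] = 0; slot_b[s] = 0;
    free_slots.push_back(s);
    --slots_in_use;
  }

  // ---- logging ----------------------------------------------------------
  void log_ev(int type, int comp, int ent, int pos, double val) {
    ++ev_count[type];
    int cat;
    switch (type) {
      case EV_SITE_PASS: case EV_SITE_TRIGGER: cat = REC_SITE; break;
      case EV_MET_ACT: cat = REC_MET; break;
      case EV_RNA_MARK: case EV_COMP_DESTROY: cat = REC_RNA; break;
      case EV_TL_INIT: case EV_TL_COMPLETE: case EV_TL_DROP: case EV_TL_TT:
        cat = REC_TL; break;
      default: cat = REC_TX;
    }
    if (!(rec_mask & cat)) return;
    ev_time.push_back(t); ev_type.push_back(type); ev_comp.push_back(comp);
    ev_ent.push_back(ent); ev_pos.push_back(pos); ev_val.push_back(val);
  }

  // ---- samplers ---------------------------------------------------------
  double sample_toc() {
    if (P.toc_sd <= 0) return P.toc_mean;
    double x;
    do { x = P.toc_mean + P.toc_sd * norm_rand(); } while (x <= 0.0);
    return x;
  }

  // ---- propensities -----------------------------------------------------
  bool start_region_free() const {
    return rnaps.empty() || (rnaps.back().pos - 1) >= rnap_excl;
  }
  double prop_promoter() const {
    if (prom_state == PR_FREE)
      return free_rnap > 0 ? (P.k_eff / P.n_rnap) * free_rnap : 0.0;
    if (prom_state == PR_OC_DONE) return start_region_free() ? P.k_m : 0.0;
    return 0.0;
  }
  double prop_pools() const {
    return P.k_fold * (double)p_prem + P.k_dec * (double)p;
  }
  bool rib_occupies(const Comp& c, int nt) const {
    return !c.ribs.empty() && c.ribs.front().pos + P.delta_rib >= nt;
  }
  // can the RNAp at index i step back one nucleotide?
  bool pyro_allowed(int i) const {
    const Rnap& r = rnaps[i];
    if (r.pos <= 1) return false;
    if (i + 1 < (int)rnaps.size() && r.pos - rnaps[i + 1].pos <= rnap_excl)
      return false;
    std::map<int, Comp>::const_iterator it = comps.find(r.comp_uid);
    if (it != comps.end() && it->second.status == ST_ELONG) {
      int f = r.pos - P.delta_rnap - 1;
      if (f >= 1 && it->second.front == f && rib_occupies(it->second, f))
        return false;  // retraction would hit a ribosome: move blocked
    }
    return true;
  }
  double prop_rnap(int i) const {
    const Rnap& r = rnaps[i];
    const Rnap* ahead  = (i > 0) ? &rnaps[i - 1] : 0;
    const Rnap* behind = (i + 1 < (int)rnaps.size()) ? &rnaps[i + 1] : 0;
    switch (r.phase) {
      case PH_STEPPING:
        return (r.pos <= 10) ? P.k_a_near : P.k_a_far;
      case PH_ACTIVATED: {
        double a = P.k_p + P.k_ar + P.k_ec + P.k_pre;
        bool abut_ahead = ahead && (ahead->pos - r.pos == rnap_excl);
        if (r.pos < L && !abut_ahead) a += P.k_m;                 // elongation (3)
        if (abut_ahead && ahead->phase == PH_PAUSED) a += P.k_m;  // collision pause (7)
        if (P.k_pyro > 0 && pyro_allowed(i)) a += P.k_pyro;       // (11)
        if (r.pos == L) a += P.k_f;                               // completion (12)
        return a;
      }
      case PH_PAUSED: {
        double a = r.release_rate;
        if (behind && (r.pos - behind->pos == rnap_excl) &&
            behind->phase == PH_ACTIVATED)
          a += P.k_m;                                             // collision release (6)
        return a;
      }
      case PH_ARRESTED:
      case PH_EDITING:
        return r.release_rate;
    }
    return 0.0;
  }
  bool comp_init_eligible(const Comp& c) const {
    if (c.marked || c.status == ST_PREM) return false;
    if (c.front < rbs_len) return false;
    if (free_rib <= 0) return false;
    if (!c.ribs.empty() && c.ribs.back().pos < rbs_len + P.delta_rib + 1)
      return false;  // RBS still under the previous ribosome's footprint
    return true;
  }
  double prop_comp(const Comp& c) const {
    double a = 0.0;
    if (comp_init_eligible(c)) a += P.k_tr;                       // initiation (14)
    if (!c.marked && c.status != ST_PREM && c.front >= rbs_len)
      a += P.k_dr;                                                // degradation (13)
    return a;
  }
  double prop_rib(const Comp& c, int j) const {
    const Rib& b = c.ribs[j];
    const Rib* ahead  = (j > 0) ? &c.ribs[j - 1] : 0;
    const Rib* behind = (j + 1 < (int)c.ribs.size()) ? &c.ribs[j + 1] : 0;
    double a = P.k_drop + P.k_tt;
    if (b.awaiting) {
      int codon = b.pos / 3;
      a += (codon == n_codons) ? P.k_trans_f : codon_rate[codon - 1];
      if (P.k_bt > 0 && codon >= 2 &&
          !(c.marked && j == (int)c.ribs.size() - 1) &&
          !(behind && b.pos - behind->pos < rib_excl + 3))
        a += P.k_bt;                                              // back-translocation (19)
    } else {
      if (b.pos + 1 <= c.front && !(ahead && ahead->pos - b.pos == rib_excl))
        a += P.k_tm;                                              // translocation (15-17)
    }
    return a;
  }

  // ---- propensity refresh ----------------------------------------------
  void upd_promoter() { tree.set(PROM_SLOT, prop_promoter()); }
  void upd_pools()    { tree.set(POOLS_SLOT, prop_pools()); }
  void upd_rnap(int i) { tree.set(rnaps[i].slot, prop_rnap(i)); }
  void upd_comp(Comp& c) { tree.set(c.slot, prop_comp(c)); }
  void upd_rib(Comp& c, int j) { tree.set(c.ribs[j].slot, prop_rib(c, j)); }
  void upd_rnap_neighbourhood(int i) {
    if (i > 0) upd_rnap(i - 1);
    upd_rnap(i);
    if (i + 1 < (int)rnaps.size()) upd_rnap(i + 1);
    upd_promoter();
  }
  void upd_all_comps() {
    for (std::map<int, Comp>::iterator it = comps.begin(); it != comps.end(); ++it)
      upd_comp(it->second);
  }
  void free_rib_return(int n) {  // give n ribosomes back to the pool
    bool was_zero = (free_rib == 0);
    free_rib += n;
    if (was_zero) upd_all_comps();
  }

  // ---- compartment lifecycle -------------------------------------------
  Comp& comp_of(int uid) {
    std::map<int, Comp>::iterator it = comps.find(uid);
    if (it == comps.end()) stop("internal error: unknown compartment");
    return it->second;
  }
  void uncount(Comp& c) { if (c.counted) { c.counted = false; --mrna; } }
  void maybe_count(Comp& c) {
    if (!c.counted && !c.marked && c.status != ST_PREM && c.front >= rbs_len) {
      c.counted = true; ++mrna;
    }
  }
  // a compartment may be destroyed once no ribosome is bound AND no RNAp is
  // still transcribing it (degradation marking does not abort transcription)
  void maybe_destroy(Comp& c) {
    if (!c.ribs.empty()) return;
    if (c.status == ST_PREM || (c.marked && c.status != ST_ELONG))
      destroy_comp(c);
  }
  void destroy_comp(Comp& c) {
    if (!c.ribs.empty())
      stop("internal error: destroying compartment with bound ribosomes");
    uncount(c);
    log_ev(EV_COMP_DESTROY, c.uid, 0, 0, 0.0);
    free_slot(c.slot);
    comps.erase(c.uid);
  }
  // advance exposure front to match RNAp position; refresh gates it opens
  void advance_front(Comp& c, int rnap_pos) {
    int nf = rnap_pos - P.delta_rnap - 1;
    if (nf > c.front) {
      c.front = nf;
      maybe_count(c);
      upd_comp(c);
      if (!c.ribs.empty()) upd_rib(c, 0);  // leading ribosome may unstall
    }
  }

  // ---- site annotations -------------------------------------------------
  void site_check(Rnap& r) {
    if (r.pos > L || site_kind[r.pos] < 0 || r.pos <= r.last_site_pos) return;
    r.last_site_pos = r.pos;
    log_ev(EV_SITE_PASS, r.comp_uid, r.uid, r.pos, 0.0);
    double u = unif_rand();
    if (u < site_prob[r.pos]) {
      r.phase = (site_kind[r.pos] == 0) ? PH_PAUSED : PH_ARRESTED;
      r.release_rate = 1.0 / site_dur[r.pos];
      log_ev(EV_SITE_TRIGGER, r.comp_uid, r.uid, r.pos, site_dur[r.pos]);
    }
  }

  // ---- RNAp removal (premature termination / detach / completion) -------
  void remove_rnap(int i) {
    free_slot(rnaps[i].slot);
    rnaps.erase(rnaps.begin() + i);
    ++free_rnap;
    if (i > 0) upd_rnap(i - 1);
    if (i < (int)rnaps.size()) upd_rnap(i);
    upd_promoter();
  }

  // ---- reaction effects -------------------------------------------------
  void fire_promoter(double u) {
    if (prom_state == PR_FREE) {                       // binding, reaction (1)
      (void)u;
      --free_rnap;
      prom_state = PR_OC_PENDING;
      oc_time = t + sample_toc();
      log_ev(EV_TX_BIND, 0, 0, 0, 0.0);
      upd_promoter();
    } else {                                           // clearance, reaction (2)
      Rnap r;
      r.uid = next_rnap_uid++; r.pos = 1; r.phase = PH_STEPPING;
      r.release_rate = 0.0; r.last_site_pos = 0;
      Comp c;
      c.uid = next_comp_uid++; c.front = 0; c.status = ST_ELONG;
      c.marked = false; c.counted = false;
      c.slot = alloc_slot(ENT_COMP, c.uid, 0);
      r.comp_uid = c.uid;
      r.slot = alloc_slot(ENT_RNAP, r.uid, 0);
      comps[c.uid] = c;
      rnaps.push_back(r);
      prom_state = PR_FREE;
      log_ev(EV_TX_CLEAR, c.uid, r.uid, 1, 0.0);
      int i = (int)rnaps.size() - 1;
      site_check(rnaps[i]);
      upd_comp(comps[c.uid]);
      upd_rnap_neighbourhood(i);
    }
  }

  void release_open_complex() {
    prom_state = PR_OC_DONE;
    log_ev(EV_TX_OC, 0, 0, 0, 0.0);
    upd_promoter();
  }

  void fire_rnap(int i, double u) {
    Rnap& r = rnaps[i];
    const Rnap* ahead  = (i > 0) ? &rnaps[i - 1] : 0;
    const Rnap* behind = (i + 1 < (int)rnaps.size()) ? &rnaps[i + 1] : 0;
    double rem = u * tree.val[r.slot];

    if (r.phase == PH_STEPPING) {                      // activation (4)
      r.phase = PH_ACTIVATED;
      upd_rnap_neighbourhood(i);
      return;
    }
    if (r.phase == PH_PAUSED || r.phase == PH_ARRESTED || r.phase == PH_EDITING) {
      // spontaneous release, or collision release (6) for paused RNAps;
      // both restore the activated phase
      r.phase = PH_ACTIVATED;
      r.release_rate = 0.0;
      upd_rnap_neighbourhood(i);
      return;
    }

    // activated phase: pick among competing channels
    bool abut_ahead = ahead && (ahead->pos - r.pos == rnap_excl);
    if (r.pos < L && !abut_ahead) {                    // elongation (3)
      if (rem < P.k_m) {
        ++r.pos;
        r.phase = PH_STEPPING;
        site_check(r);
        Comp& c = comp_of(r.comp_uid);
        if (c.status == ST_ELONG) advance_front(c, r.pos);
        upd_rnap_neighbourhood(i);
        return;
      }
      rem -= P.k_m;
    }
    if (abut_ahead && ahead->phase == PH_PAUSED) {     // collision-induced pause (7)
      if (rem < P.k_m) {
        r.phase = PH_PAUSED;
        r.release_rate = 1.0 / P.tau_p;
        upd_rnap_neighbourhood(i);
        return;
      }
      rem -= P.k_m;
    }
    if (rem < P.k_p) {                                 // ubiquitous pause (5)
      r.phase = PH_PAUSED;
      r.release_rate = 1.0 / P.tau_p;
      upd_rnap_neighbourhood(i);
      return;
    }
    rem -= P.k_p;
    if (rem < P.k_ar) {                                // arrest (8)
      r.phase = PH_ARRESTED;
      r.release_rate = 1.0 / P.tau_ar;
      upd_rnap_neighbourhood(i);
      return;
    }
    rem -= P.k_ar;
    if (rem < P.k_ec) {                                // editing (9)
      r.phase = PH_EDITING;
      r.release_rate = 1.0 / P.tau_c;
      upd_rnap_neighbourhood(i);
      return;
    }
    rem -= P.k_ec;
    if (rem < P.k_pre) {                               // premature termination (10)
      Comp& c = comp_of(r.comp_uid);
      log_ev(EV_TX_PREMATURE, c.uid, r.uid, r.pos, 0.0);
      c.status = ST_PREM;
      uncount(c);
      remove_rnap(i);
      if (c.ribs.empty()) destroy_comp(c); else upd_comp(c);
      return;
    }
    rem -= P.k_pre;
    if (P.k_pyro > 0 && pyro_allowed(i)) {             // pyrophosphorolysis (11)
      if (rem < P.k_pyro) {
        --r.pos;
        r.phase = PH_STEPPING;
        Comp& c = comp_of(r.comp_uid);
        if (c.status == ST_ELONG) {
          int nf = r.pos - P.delta_rnap - 1;
          if (nf < 0) nf = 0;
          if (nf < c.front) {
            c.front = nf;
            if (c.front < rbs_len) uncount(c);
            upd_comp(c);
            if (!c.ribs.empty()) upd_rib(c, 0);
          }
        }
        upd_rnap_neighbourhood(i);
        return;
      }
      rem -= P.k_pyro;
    }
    if (r.pos == L) {                                  // completion (12)
      Comp& c = comp_of(r.comp_uid);
      log_ev(EV_TX_COMPLETE, c.uid, r.uid, r.pos, 0.0);
      c.status = ST_COMPLETE;
      c.front = L;
      maybe_count(c);
      remove_rnap(i);
      if (c.marked && c.ribs.empty()) { destroy_comp(c); return; }
      upd_comp(c);
      if (!c.ribs.empty()) upd_rib(c, 0);
      return;
    }
    // if round-off left us here, treat as a pause (harmless, never expected)
    r.phase = PH_PAUSED;
    r.release_rate = 1.0 / P.tau_p;
    upd_rnap_neighbourhood(i);
  }

  void fire_comp(Comp& c, double u) {
    double a_init = comp_init_eligible(c) ? P.k_tr : 0.0;
    double rem = u * tree.val[c.slot];
    if (rem < a_init) {                                // translation initiation (14)
      --free_rib;
      Rib b;
      b.uid = next_rib_uid++; b.pos = 3; b.awaiting = true;
      b.steps = 0; b.peptide = 0; b.max_codon = 0;
      b.slot = alloc_slot(ENT_RIB, b.uid, c.uid);
      c.ribs.push_back(b);
      log_ev(EV_TL_INIT, c.uid, b.uid, 3, 0.0);
      int j = (int)c.ribs.size() - 1;
      upd_rib(c, j);
      if (j > 0) upd_rib(c, j - 1);
      upd_comp(c);
      if (free_rib == 0) upd_all_comps();
      return;
    }
    // degradation-marking, reaction (13)
    c.marked = true;
    uncount(c);
    log_ev(EV_RNA_MARK, c.uid, 0, 0, 0.0);
    if (c.ribs.empty() && c.status != ST_ELONG) { destroy_comp(c); return; }
    upd_comp(c);
    if (!c.ribs.empty())
      upd_rib(c, (int)c.ribs.size() - 1);  // trailing ribosome loses back-translocation
  }

  void remove_rib(Comp& c, int j) {
    free_slot(c.ribs[j].slot);
    c.ribs.erase(c.ribs.begin() + j);
    if (j > 0) upd_rib(c, j - 1);
    if (j < (int)c.ribs.size()) upd_rib(c, j);
    upd_comp(c);
  }

  void detach_rnap_of(Comp& c) {
    for (int i = 0; i < (int)rnaps.size(); ++i) {
      if (rnaps[i].comp_uid == c.uid) {
        log_ev(EV_TX_DETACH, c.uid, rnaps[i].uid, rnaps[i].pos, 0.0);
        remove_rnap(i);
        return;
      }
    }
  }

  void fire_rib(Comp& c, int j, double u) {
    Rib& b = c.ribs[j];
    const Rib* ahead  = (j > 0) ? &c.ribs[j - 1] : 0;
    const Rib* behind = (j + 1 < (int)c.ribs.size()) ? &c.ribs[j + 1] : 0;
    double rem = u * tree.val[b.slot];

    if (b.awaiting) {
      int codon = b.pos / 3;
      double a_act = (codon == n_codons) ? P.k_trans_f : codon_rate[codon - 1];
      if (rem < a_act) {
        if (codon == n_codons) {                       // elongation completion (22)
          log_ev(EV_TL_COMPLETE, c.uid, b.uid, b.pos, (double)b.peptide);
          remove_rib(c, j);
          free_rib_return(1);
          ++p_prem;
          upd_pools();
          maybe_destroy(c);
          return;
        }
        // codon activation (18)
        b.awaiting = false;
        b.steps = 0;
        if (codon > b.max_codon) {
          b.max_codon = codon;
          ++b.peptide;
          if (is_met[codon - 1]) log_ev(EV_MET_ACT, c.uid, b.uid, codon, 0.0);
        }
        upd_rib(c, j);
        return;
      }
      rem -= a_act;
      bool can_back = P.k_bt > 0 && codon >= 2 &&
        !(c.marked && j == (int)c.ribs.size() - 1) &&
        !(behind && b.pos - behind->pos < rib_excl + 3);
      if (can_back && rem < P.k_bt) {                  // back-translocation (19)
        b.pos -= 3;
        upd_rib(c, j);
        if (behind) upd_rib(c, j + 1);
        if (ahead) upd_rib(c, j - 1);
        upd_comp(c);
        return;
      }
      if (can_back) rem -= P.k_bt;
    } else {
      bool can_fwd = (b.pos + 1 <= c.front) && !(ahead && ahead->pos - b.pos == rib_excl);
      if (can_fwd && rem < P.k_tm) {                   // translocation (15-17)
        ++b.pos;
        ++b.steps;
        if (b.steps >= 3) b.awaiting = true;
        upd_rib(c, j);
        if (behind) upd_rib(c, j + 1);
        if (ahead) upd_rib(c, j - 1);
        if (j == (int)c.ribs.size() - 1) upd_comp(c);  // RBS may clear
        return;
      }
      if (can_fwd) rem -= P.k_tm;
    }
    if (rem < P.k_drop) {                              // drop-off (20)
      log_ev(EV_TL_DROP, c.uid, b.uid, b.pos, 0.0);
      remove_rib(c, j);
      free_rib_return(1);
      maybe_destroy(c);
      return;
    }
    // trans-translation (21): all ribosomes released, strand destroyed
    int nr = (int)c.ribs.size();
    log_ev(EV_TL_TT, c.uid, b.uid, b.pos, (double)nr);
    for (int k = 0; k < nr; ++k) free_slot(c.ribs[k].slot);
    c.ribs.clear();
    free_rib_return(nr);
    if (c.status == ST_ELONG) detach_rnap_of(c);
    destroy_comp(c);
  }

  void fire_pools(double u) {
    double a_fold = P.k_fold * (double)p_prem;
    double rem = u * tree.val[POOLS_SLOT];
    if (rem < a_fold) { --p_prem; ++p; }               // folding/activation (23)
    else { --p; }                                      // protein degradation (24)
    upd_pools();
  }

  // ---- invariants -------------------------------------------------------
  void check_invariants() const {
    for (int i = 0; i + 1 < (int)rnaps.size(); ++i)
      if (rnaps[i].pos - rnaps[i + 1].pos < rnap_excl)
        stop("invariant violation: RNAp footprints overlap at t=%f", t);
    long long bound = 0;
    for (std::map<int, Comp>::const_iterator it = comps.begin();
         it != comps.end(); ++it) {
      const Comp& c = it->second;
      if (c.front > L) stop("invariant violation: exposure front beyond gene end");
      for (int j = 0; j < (int)c.ribs.size(); ++j) {
        if (c.ribs[j].pos > c.front)
          stop("invariant violation: ribosome beyond exposure front at t=%f", t);
        if (j + 1 < (int)c.ribs.size() &&
            c.ribs[j].pos - c.ribs[j + 1].pos < rib_excl)
          stop("invariant violation: ribosome footprints overlap at t=%f", t);
      }
      bound += (long long)c.ribs.size();
    }
    int on_prom = (prom_state == PR_FREE) ? 0 : 1;
    if (free_rnap + (int)rnaps.size() + on_prom != P.n_rnap)
      stop("invariant violation: RNAp conservation broken at t=%f", t);
    if ((long long)free_rib + bound != (long long)P.n_rib)
      stop("invariant violation: ribosome conservation broken at t=%f", t);
    int counted = 0;
    for (std::map<int, Comp>::const_iterator it = comps.begin();
         it != comps.end(); ++it)
      if (it->second.counted) ++counted;
    if (counted != mrna)
      stop("invariant violation: mRNA observable out of sync at t=%f", t);
    if (p_prem < 0 || p < 0) stop("invariant violation: negative protein count");
  }

  // ---- sampling ---------------------------------------------------------
  void record_sample(double ts) {
    s_time.push_back(ts);
    s_mrna.push_back(mrna);
    s_pprem.push_back((int)p_prem);
    s_p.push_back((int)p);
    s_free_rnap.push_back(free_rnap);
    s_free_rib.push_back(free_rib);
    s_rnaps.push_back((int)rnaps.size());
    long long bound = 0;
    for (std::map<int, Comp>::const_iterator it = comps.begin();
         it != comps.end(); ++it)
      bound += (long long)it->second.ribs.size();
    s_ribs.push_back((int)bound);
    s_comps.push_back((int)comps.size());
    if (check_inv) check_invariants();
  }
  void record_kymo(double ts) {
    for (int i = 0; i < (int)rnaps.size(); ++i) {
      ky_time.push_back(ts); ky_is_rib.push_back(0);
      ky_ent.push_back(rnaps[i].uid); ky_comp.push_back(rnaps[i].comp_uid);
      ky_pos.push_back(rnaps[i].pos);
    }
    for (std::map<int, Comp>::const_iterator it = comps.begin();
         it != comps.end(); ++it) {
      const Comp& c = it->second;
      for (int j = 0; j < (int)c.ribs.size(); ++j) {
        ky_time.push_back(ts); ky_is_rib.push_back(1);
        ky_ent.push_back(c.ribs[j].uid); ky_comp.push_back(c.uid);
        ky_pos.push_back(c.ribs[j].pos);
      }
    }
  }

  // ---- main loop --------------------------------------------------------
  void run(double t_end, double sample_dt, double max_events) {
    double next_sample = 0.0;
    double next_kymo = (kymo_dt > 0) ? 0.0 : R_PosInf;
    long long rebuild_at = 1LL << 24;

    tree.set(PROM_SLOT, prop_promoter());
    tree.set(POOLS_SLOT, prop_pools());

    for (;;) {
      double A = tree.tot;
      double t_rxn = (A > 0) ? t + exp_rand() / A : R_PosInf;
      double t_del = (prom_state == PR_OC_PENDING) ? oc_time : R_PosInf;
      double t_fire = (t_del <= t_rxn) ? t_del : t_rxn;

      // flush sampling grid up to the next event (state before the event)
      while (next_sample <= t_fire && next_sample <= t_end) {
        record_sample(next_sample);
        next_sample += sample_dt;
      }
      while (next_kymo <= t_fire && next_kymo <= t_end) {
        record_kymo(next_kymo);
        next_kymo += kymo_dt;
      }
      if (t_fire > t_end) { t = t_end; break; }
      t = t_fire;

      if (t_del <= t_rxn) {
        release_open_complex();
      } else {
        double u = unif_rand();
        int slot = tree.sample(std::max(u * A, 1e-300));
        double u2 = unif_rand();
        switch (slot_type[slot]) {
          case ENT_PROMOTER: fire_promoter(u2); break;
          case ENT_POOLS:    fire_pools(u2); break;
          case ENT_RNAP: {
            int i = -1;
            for (int k = 0; k < (int)rnaps.size(); ++k)
              if (rnaps[k].uid == slot_a[slot]) { i = k; break; }
            if (i < 0) stop("internal error: stale RNAp slot");
            fire_rnap(i, u2);
            break;
          }
          case ENT_COMP: fire_comp(comp_of(slot_a[slot]), u2); break;
          case ENT_RIB: {
            Comp& c = comp_of(slot_b[slot]);
            int j = -1;
            for (int k = 0; k < (int)c.ribs.size(); ++k)
              if (c.ribs[k].uid == slot_a[slot]) { j = k; break; }
            if (j < 0) stop("internal error: stale ribosome slot");
            fire_rib(c, j, u2);
            break;
          }
          default: stop("internal error: fired an empty slot");
        }
      }

      if (++n_events >= rebuild_at) { tree.rebuild(); rebuild_at += 1LL << 24; }
      if (n_events > (long long)max_events)
        stop("event budget exceeded (%g events); shorten the run", max_events);
      if ((n_events & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    }
  }
};

static double pget(List p, const char* nm) {
  if (!p.containsElementNamed(nm)) stop("missing kinetic parameter '%s'", nm);
  return as<double>(p[nm]);
}

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(List gene, List params, double t_end, double sample_interval,
                List control) {
  Engine E;
  Params& P = E.P;
  P.k_init = pget(params, "k_init");
  P.toc_mean = pget(params, "toc_mean");  P.toc_sd = pget(params, "toc_sd");
  P.k_m = pget(params, "k_m");
  P.k_a_far = pget(params, "k_a_far");    P.k_a_near = pget(params, "k_a_near");
  P.k_p = pget(params, "k_p");            P.tau_p = pget(params, "tau_p");
  P.k_ar = pget(params, "k_ar");          P.tau_ar = pget(params, "tau_ar");
  P.k_ec = pget(params, "k_ec");          P.tau_c = pget(params, "tau_c");
  P.k_pre = pget(params, "k_pre");        P.k_pyro = pget(params, "k_pyro");
  P.k_f = pget(params, "k_f");            P.k_dr = pget(params, "k_dr");
  P.k_tr = pget(params, "k_trans_init");  P.k_tm = pget(params, "k_tm");
  P.k_bt = pget(params, "k_bt");          P.k_drop = pget(params, "k_drop");
  P.k_tt = pget(params, "k_tt");          P.k_trans_f = pget(params, "k_trans_f");
  P.k_fold = pget(params, "k_fold");      P.k_dec = pget(params, "k_dec");
  P.delta_rnap = (int)pget(params, "delta_rnap");
  P.delta_rib = (int)pget(params, "delta_rib");
  P.n_rnap = (int)pget(params, "n_rnap");
  P.n_rib = (int)pget(params, "n_rib");
  P.k_eff = pget(params, "k_eff");

  E.L = as<int>(gene["length"]);
  E.n_codons = E.L / 3;
  E.codon_rate = as<std::vector<double> >(gene["codon_rates"]);
  LogicalVector met = gene["is_met"];
  E.is_met.assign(E.n_codons, 0);
  for (int i = 0; i < E.n_codons; ++i) E.is_met[i] = met[i] ? 1 : 0;
  if ((int)E.codon_rate.size() != E.n_codons)
    stop("codon rate vector does not match gene length");

  E.site_kind.assign(E.L + 1, -1);
  E.site_prob.assign(E.L + 1, 0.0);
  E.site_dur.assign(E.L + 1, 0.0);
  if (gene.containsElementNamed("site_pos")) {
    IntegerVector sp = gene["site_pos"];
    IntegerVector sk = gene["site_kind"];
    NumericVector spr = gene["site_prob"];
    NumericVector sd = gene["site_dur"];
    for (int i = 0; i < sp.size(); ++i) {
      if (sp[i] < 1 || sp[i] > E.L) stop("site position out of range");
      E.site_kind[sp[i]] = (signed char)sk[i];
      E.site_prob[sp[i]] = spr[i];
      E.site_dur[sp[i]] = sd[i];
    }
  }

  E.rnap_excl = 2 * P.delta_rnap + 1;
  E.rib_excl = 2 * P.delta_rib + 1;
  E.rbs_len = 2 * P.delta_rib + 1;
  E.free_rnap = P.n_rnap;
  E.free_rib = P.n_rib;

  E.rec_mask = as<int>(control["record_mask"]);
  E.check_inv = as<bool>(control["check_invariants"]);
  E.kymo_dt = as<double>(control["kymograph_interval"]);
  double max_events = as<double>(control["max_events"]);

  E.tree.init(1024);
  E.PROM_SLOT = E.alloc_slot(ENT_PROMOTER, 0, 0);
  E.POOLS_SLOT = E.alloc_slot(ENT_POOLS, 0, 0);
  int baseline_slots = E.slots_in_use;

  E.run(t_end, sample_interval, max_events);

  DataFrame ts = DataFrame::create(
    _["time"] = E.s_time, _["mrna"] = E.s_mrna, _["p_prem"] = E.s_pprem,
    _["p"] = E.s_p, _["free_rnap"] = E.s_free_rnap,
    _["free_rib"] = E.s_free_rib, _["rnap_on_dna"] = E.s_rnaps,
    _["rib_bound"] = E.s_ribs, _["compartments"] = E.s_comps);
  DataFrame ev = DataFrame::create(
    _["time"] = E.ev_time, _["type"] = E.ev_type, _["comp_id"] = E.ev_comp,
    _["entity_id"] = E.ev_ent, _["position"] = E.ev_pos, _["value"] = E.ev_val);
  DataFrame ky = DataFrame::create(
    _["time"] = E.ky_time, _["is_ribosome"] = E.ky_is_rib,
    _["entity_id"] = E.ky_ent, _["comp_id"] = E.ky_comp,
    _["position"] = E.ky_pos);
  List counters = List::create(
    _["n_events"] = (double)E.n_events,
    _["event_type_counts"] = NumericVector(E.ev_count.begin() + 1, E.ev_count.end()),
    _["slots_in_use_final"] = E.slots_in_use,
    _["slots_baseline"] = baseline_slots,
    _["live_compartments"] = (int)E.comps.size(),
    _["final_mrna"] = E.mrna,
    _["final_p_prem"] = (double)E.p_prem,
    _["final_p"] = (double)E.p,
    _["final_free_rnap"] = E.free_rnap,
    _["final_free_rib"] = E.free_rib);
  return List::create(_["timeseries"] = ts, _["events"] = ev,
                      _["kymograph"] = ky, _["counters"] = counters);
}
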