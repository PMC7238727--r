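ortholog_id	temporal_class	provenance
OG0001	early	synthetic stand-in for a cultured-phage time-course annotation
OG0002	early	synthetic stand-in for a cultured-phage time-course annotation
OG0003	early	synthetic stand-in for a cultured-phage time-course annotation
OG0004	middle	synthetic stand-in for a cultured-phage time-course annotation
OG0005	middle	synthetic stand-in for a cultured-phage time-course annotation
OG0006	middle	synthetic stand-in for a cultured-phage time-course annotation
OG0007	middle	synthetic stand-in for a cultured-phage time-course annotation
OG0008	middle	synthetic stand-in for a cultured-phage time-course annotation
OG0009	middle	synthetic stand-in for a cultured-phage time-course annotation
OG0010	middle	synthetic stand-in for a cultured-phage time-course annotation
OG0011	middle	synthetic stand-in for a cultured-phage time-course annotation
OG0012	middle	synthetic stand-in for a cultured-phage time-course annotation
OG0013	middle	synthetic stand-in for a cultured-phage time-course annotation
OG0014	middle	synthetic stand-in for a cultured-phage time-course annotation
OG0015	late	synthetic stand-in for a cultured-phage time-course annotation
OG0016	late	synthetic stand-in for a cultured-phage time-course annotation
OG0017	late	synthetic stand-in for a cultured-phage time-course annotation
OG0018	late	synthetic stand-in for a cultured-phage time-course annotation
OG0019	late	synthetic stand-in for a cultured-phage time-course annotation
OG0020	late	synthetic stand-in for a cultured-phage time-course annotation
OG0021	late	synthetic stand-in for a cultured-phage time-course annotation
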