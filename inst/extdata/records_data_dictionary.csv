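column,type,units,description
athlete_id,character,,opaque athlete identifier unique within the roster
match_id,character,,opaque match identifier
tournament_id,character,,tournament the match belongs to
game_number,integer,,position of the match in its tournament (1-6)
mass_kg,numeric,kg,athlete body mass measured pre-match
contacts,integer,count,video-coded tackles/carries/rucks for the player-match
LS_LA,numeric,m,distance at low speed and mild acceleration (0 < a <= 2 m/s^2)
LS_HA,numeric,m,distance at low speed and hard acceleration (a > 2 m/s^2)
LS_LD,numeric,m,distance at low speed and mild deceleration (-2 <= a <= 0 m/s^2)
LS_HD,numeric,m,distance at low speed and hard deceleration (a < -2 m/s^2)
MS_LA,numeric,m,distance at moderate speed and mild acceleration
MS_HA,numeric,m,distance at moderate speed and hard acceleration
MS_LD,numeric,m,distance at moderate speed and mild deceleration
MS_HD,numeric,m,distance at moderate speed and hard deceleration
HS_LA,numeric,m,distance at high speed and mild acceleration
HS_HA,numeric,m,distance at high speed and hard acceleration
HS_LD,numeric,m,distance at high speed and mild deceleration
HS_HD,numeric,m,distance at high speed and hard deceleration
total_m,numeric,m,total on-field non-halftime distance (sum of the 12 cells)
playing_time_min,numeric,min,on-field non-halftime playing time
rpe_au,numeric,au,self-reported rating of perceived exertion (0-10; NA = not reported)
srpe_au,numeric,au,session RPE = rpe_au x playing_time_min (NA when RPE missing)
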